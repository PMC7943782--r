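test_that("haplotype collapsing handles identity, distinctness and N-overlap", {
  expect_equal(collapse_haplotypes(rep("ACGTACGT", 5))$abundances, 5L)
  set.seed(21)
  three <- c(rand_seq(40), rand_seq(40), rand_seq(40))
  tab <- collapse_haplotypes(three)
  expect_equal(tab$S_obs, 3L)
  expect_equal(tab$f1, 3L)
  tab2 <- collapse_haplotypes(c("AAAA", "AAAA", "AAAT"))
  expect_equal(tab2$abundances, c(2L, 1L))
  expect_equal(tab2$f1, 1L)
  expect_equal(tab2$f2, 1L)
  # an N-bearing sequence matches on the overlap
  expect_equal(collapse_haplotypes(c("ACNT", "ACGT"))$S_obs, 1L)
  # transitive closure: ambiguous middle sequence bridges two haplotypes
  bridge <- c("AAAA", "AANA", "AACA")
  expect_equal(collapse_haplotypes(bridge)$S_obs, 1L)
  expect_equal(collapse_haplotypes(bridge, strict = TRUE)$S_obs, 3L)
})

test_that("analytic rarefaction equals exhaustive subset enumeration", {
  # closed-form hand case: abundances [2,1], m = 2 -> 5/3
  expect_equal(rarefied_richness(c(2, 1), 2), 5 / 3)
  # identities
  tab <- haplotype_table(c(4, 3, 1, 1))
  expect_equal(rarefied_richness(tab, tab$n), tab$S_obs)
  expect_equal(rarefied_richness(tab, 1), 1)
  expect_error(rarefied_richness(tab, 0), "1 <= m <= n")
  expect_error(rarefied_richness(tab, tab$n + 1), "1 <= m <= n")
  # enumeration oracle over all partitions of small n
  for (n in c(5, 7, 9)) {
    for (part in partitions_of(n)) {
      for (m in seq_len(n)) {
        expect_equal(rarefied_richness(part, m), rarefaction_enum(part, m),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("analytic rarefaction agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(22)
  for (r in 1:20) {
    x <- as.integer(rmultinom(1, 60, rexp(8)))
    x <- x[x > 0]
    m <- sample(sum(x), 1)
    v <- suppressWarnings(as.numeric(vegan::rarefy(x, sample = m)))
    expect_equal(rarefied_richness(x, m), v, tolerance = 1e-8)
  }
})

test_that("Chao1 asymptote matches closed-form hand evaluations", {
  expect_equal(chao1_richness(c(3, 2)), 2)
  expect_equal(chao1_richness(c(3, 2, 1, 1, 1)), 6.3125)
  for (k in c(2, 5, 11)) { # all singletons: symbolic form
    expect_equal(chao1_richness(rep(1, k)), k + (k - 1) / k * k * (k - 1) / 2)
  }
  expect_gte(chao1_richness(c(5, 1, 1)), 3)
})

test_that("extrapolation interpolates between S_obs and the asymptote", {
  x <- c(3, 2, 1, 1, 1)
  expect_equal(extrapolated_richness(x, 0), 5)
  expect_equal(extrapolated_richness(x, 1e6), chao1_richness(x),
               tolerance = 1e-6)
  # closed-form re-derivation with f0_hat = 1.3125, f1 = 3, n = 8
  m8 <- 5 + 1.3125 * (1 - (1 - 3 / (8 * 1.3125 + 3))^8)
  expect_equal(extrapolated_richness(x, 8), m8)
  # no singletons -> flat curve
  expect_equal(extrapolated_richness(c(3, 2), 50), 2)
  # monotone nondecreasing, bounded by the asymptote
  curve <- extrapolated_richness(x, 0:50)
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve <= chao1_richness(x) + 1e-12))
})

test_that("rarefaction curves are nondecreasing and concave", {
  set.seed(23)
  for (r in 1:10) {
    x <- as.integer(rmultinom(1, 40, rexp(10))); x <- x[x > 0]
    s <- rarefied_richness(x, seq_len(sum(x)))
    expect_true(all(diff(s) >= -1e-12))
    expect_true(all(diff(diff(s)) <= 1e-12))
  }
})

test_that("completeness is observed over estimated richness with the n >= 6 rule", {
  expect_equal(sampling_completeness(c(3, 2))$completeness, 1)
  cp <- sampling_completeness(c(3, 2, 1, 1, 1))
  expect_equal(cp$completeness, 5 / 6.3125)
  expect_true(cp$included)
  expect_false(sampling_completeness(c(2, 1, 1, 1))$included)
})

test_that("near-exhaustive sampling drives completeness to one", {
  # n >> K: every haplotype observed with high probability
  set.seed(24)
  compl <- replicate(10, {
    ab <- sample_abundances(0.8, K = 6, n = 500)
    sampling_completeness(ab[ab > 0])$completeness
  })
  expect_gte(mean(compl), 0.95)
})

test_that("octave classes follow the eight geometric bins with clamping", {
  oc <- octave_profile(list(c(1)))
  expect_equal(unname(which(oc$per_species[1, ] > 0)), 1L)
  oc7 <- octave_profile(list(c(7)))
  expect_equal(names(which(oc7$per_species[1, ] > 0)), "4-7")
  oc255 <- octave_profile(list(c(255)))
  expect_equal(names(which(oc255$per_species[1, ] > 0)), "128-255")
  expect_warning(oc256 <- octave_profile(list(c(256))), "clamped")
  expect_equal(names(which(oc256$per_species[1, ] > 0)), "128-255")
  oc3 <- octave_profile(list(c(1, 1, 2)))
  expect_equal(unname(oc3$per_species[1, ]), c(2 / 3, 1 / 3, rep(0, 6)))
  # per-species frequencies sum to one
  set.seed(25)
  tabs <- replicate(6, {
    x <- as.integer(rmultinom(1, 50, rexp(12))); x[x > 0]
  }, simplify = FALSE)
  oc <- octave_profile(tabs)
  expect_equal(unname(rowSums(oc$per_species)), rep(1, 6))
})

test_that("a geometric cohort has the singleton octave as its modal class", {
  ds <- generate_dataset(barcode_sim_config(seed = 31))
  lib <- ds$library
  idx <- split(seq_len(n_specimens(lib)), lib$metadata$species)
  idx <- idx[lengths(idx) >= 6]
  tabs <- lapply(idx, function(i) collapse_haplotypes(lib$sequences[i]))
  oc <- octave_profile(tabs)
  expect_equal(unname(which.max(oc$mean)), 1L)
})
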