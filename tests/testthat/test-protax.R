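# Small fully separable reference library: one genus, two species, three
# identical reference barcodes each, species 20 substitutions apart.
separable_toy <- function() {
  set.seed(55)
  base <- rand_seq(658)
  other <- sub_at(base, 1:20)
  toy_library(species = rep(c("GenA_sp1", "GenA_sp2"), each = 3),
              sequences = c(rep(base, 3), rep(other, 3)),
              genus = rep("GenA", 6))
}

test_that("node probabilities are a softmax over shared weights", {
  X <- matrix(0, 4, 2)
  expect_equal(node_probabilities(c(0, 0, 0), X), rep(0.25, 4))
  expect_equal(node_probabilities(c(3, -1, 2), matrix(c(0.5, 0.1), 1, 2)), 1)
  # one candidate two standard units closer in d_min
  X2 <- rbind(c(-2, 0), c(0, 0), c(0, 0))
  p <- node_probabilities(c(0, -5, 0), X2)
  hand <- exp(10) / (exp(10) + 2)
  expect_equal(p[1], hand)
  expect_equal(sum(p), 1)
})

test_that("the training set uses leave-one-out predictors and flags singletons", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  lv4 <- ts$levels[[4]]
  # 6 records, each with the 2 congeneric species as candidates
  expect_equal(nrow(lv4$Xmin), 6L)
  expect_equal(unname(rowSums(lv4$mask)), rep(2L, 6))
  expect_equal(lv4$n_unreachable, 0L)
  # duplicate haplotypes present: leave-one-out d_min to own species is 0
  raw_min <- lv4$Xmin * lv4$scaler$sd[1] + lv4$scaler$mean[1]
  own <- cbind(seq_len(6), lv4$label)
  expect_true(all(abs(raw_min[own]) < 1e-12))
  # standardization: training predictors have mean 0, sd 1
  expect_equal(mean(lv4$Xmin[lv4$mask]), 0, tolerance = 1e-12)
  expect_equal(sd(lv4$Xmin[lv4$mask]), 1, tolerance = 1e-12)
  # a singleton species is unreachable as its own label
  set.seed(56)
  libS <- toy_library(species = c(rep("GenA_sp1", 3), "GenA_sp2"),
                      sequences = c(rep(rand_seq(658), 3), rand_seq(658)),
                      genus = rep("GenA", 4))
  tsS <- build_training_set(libS)
  expect_equal(tsS$levels[[4]]$n_unreachable, 1L)
})

test_that("the log posterior combines multinomial likelihood and Gaussian prior", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  prior0 <- sum(dnorm(c(0, 0, 0), 0, 100, log = TRUE))
  expect_equal(protax_log_posterior(c(0, 0, 0), ts$levels[[4]]),
               6 * log(0.5) + prior0)
  # additivity: doubling every record doubles the likelihood part
  lv <- ts$levels[[4]]
  lv2 <- lv
  lv2$Xmin <- rbind(lv$Xmin, lv$Xmin)
  lv2$Xavg <- rbind(lv$Xavg, lv$Xavg)
  lv2$mask <- rbind(lv$mask, lv$mask)
  lv2$label <- c(lv$label, lv$label)
  beta <- c(0.3, -2, 0.7)
  ll <- function(l, b) protax_log_posterior(b, l) -
    sum(dnorm(b, 0, 100, log = TRUE))
  expect_equal(ll(lv2, beta), 2 * ll(lv, beta))
})

test_that("MCMC training is seed-deterministic and adapts its acceptance", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  m1 <- protax_train(ts, n_adapt = 150, n_iter = 150, seed = 4)
  m2 <- protax_train(ts, n_adapt = 150, n_iter = 150, seed = 4)
  expect_identical(m1$chains[[4]]$trace, m2$chains[[4]]$trace)
  m3 <- protax_train(ts, n_adapt = 150, n_iter = 150, seed = 5)
  expect_false(identical(m3$chains[[4]]$trace, m1$chains[[4]]$trace))
})

test_that("the MAP on a separable toy matches a grid-search oracle", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  set.seed(6)
  model <- protax_train(ts, seed = 6)
  loo <- protax_classify_loo(model, dm = ts$dm)
  expect_true(all(loo$correct_prob > 0.99))
  # oracle: best achievable mean correct-label probability at the species
  # level over a coarse beta grid
  lv <- ts$levels[[4]]
  mean_correct <- function(beta) {
    eta <- beta[1] + beta[2] * lv$Xmin + beta[3] * lv$Xavg
    eta[!lv$mask] <- -Inf
    m <- apply(eta, 1, max)
    p <- exp(eta - m) / rowSums(exp(eta - m), na.rm = TRUE)
    mean(p[cbind(seq_along(lv$label), lv$label)])
  }
  grid <- as.matrix(expand.grid(b0 = seq(-10, 10, 5),
                                b1 = seq(-30, 10, 4),
                                b2 = seq(-30, 10, 4)))
  oracle_best <- max(apply(grid, 1, mean_correct))
  map_perf <- mean_correct(model$levels[[4]]$beta)
  expect_gte(map_perf, oracle_best - 0.01)
})

test_that("classification conserves probability and decays along the path", {
  cfg <- barcode_sim_config(seed = 8, n_families = 2,
                            subfamilies_per_family = 1,
                            genera_per_subfamily = 2, species_per_genus = 3,
                            n_specimens_fixed = 8)
  ds <- generate_dataset(cfg)
  ts <- build_training_set(ds$library)
  model <- protax_train(ts, n_adapt = 400, n_iter = 400, seed = 9)
  loo <- protax_classify_loo(model, dm = ts$dm)
  # all species have >= 2 refs: species probabilities sum to exactly 1
  expect_equal(unname(rowSums(loo$species_prob)), rep(1, nrow(loo$species_prob)),
               tolerance = 1e-9)
  # monotone decay: species prob <= genus <= subfamily <= family
  md <- ds$library$metadata
  for (i in seq_len(nrow(md))) {
    pth <- c(md$family[i], md$subfamily[i], md$genus[i], md$species[i])
    probs <- vapply(pth, function(tx) loo$taxon_prob[[tx]][i], numeric(1))
    expect_true(all(diff(probs) <= 1e-12))
  }
})

test_that("leave-one-out assigns zero probability to singleton species", {
  cfg <- barcode_sim_config(seed = 12, n_families = 1,
                            subfamilies_per_family = 1,
                            genera_per_subfamily = 2, species_per_genus = 3,
                            n_specimens_fixed = c(10, 10, 1, 10, 10, 10))
  ds <- generate_dataset(cfg)
  singleton <- names(which(table(ds$library$metadata$species) == 1))
  ts <- build_training_set(ds$library)
  model <- protax_train(ts, n_adapt = 300, n_iter = 300, seed = 2)
  loo <- protax_classify_loo(model, dm = ts$dm)
  expect_equal(unname(loo$correct_prob[ds$library$metadata$species ==
                                         singleton]), 0)
})

test_that("serialized models classify identically after a round trip", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  model <- protax_train(ts, n_adapt = 200, n_iter = 200, seed = 3)
  path <- tempfile(fileext = ".json")
  write_protax_model(model, path)
  model2 <- read_protax_model(path, lib)
  loo1 <- protax_classify_loo(model, dm = ts$dm)
  loo2 <- protax_classify_loo(model2, dm = ts$dm)
  expect_equal(loo1$species_prob, loo2$species_prob, tolerance = 1e-12)
})

test_that("fresh queries are classified through the same model surface", {
  lib <- separable_toy()
  ts <- build_training_set(lib)
  model <- protax_train(ts, n_adapt = 200, n_iter = 200, seed = 3)
  q <- c(q1 = lib$sequences[[1]], q2 = lib$sequences[[4]])
  res <- protax_classify(model, q)
  expect_equal(res$assignments$top_species, c("GenA_sp1", "GenA_sp2"))
  expect_true(all(res$assignments$top_prob > 0.99))
})
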