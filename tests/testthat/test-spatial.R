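test_that("belt grids and membership follow the closed +/-1 degree rule", {
  belts <- make_belts("latitude", 35, 70)
  expect_length(belts$centers, 71)
  mem <- belt_members(belts, 40.2)
  hit <- belts$centers[vapply(mem, length, integer(1)) > 0]
  expect_equal(hit, c(39.5, 40.0, 40.5, 41.0))
  # closed boundary: a specimen exactly half_width away is included
  mem2 <- belt_members(belts, 36.0)
  expect_true(1 %in% mem2[[1]]) # first belt center 35.0, exactly 1 deg away
  # every specimen within [lo-1, hi+1] lands in at least one belt
  set.seed(61)
  x <- runif(200, 34, 71)
  counts <- Reduce(`+`, lapply(belt_members(belts, x), function(i)
    as.integer(seq_along(x) %in% i)))
  expect_true(all(counts[x >= 34 & x <= 71] >= 1))
})

test_that("great-circle distances match the haversine closed form", {
  expect_equal(mean_conspecific_distance(c(48.1, 48.1), c(9.5, 9.5)), 0)
  # one degree along a meridian: pi * 6371 / 180 km
  expect_equal(mean_conspecific_distance(c(45, 46), c(7, 7)),
               pi * 6371 / 180, tolerance = 1e-4)
  expect_true(is.na(mean_conspecific_distance(45, 7)))
  # three points: mean over all pairs, brute force
  lat <- c(40, 42, 47); lon <- c(5, 12, -3)
  pairs <- combn(3, 2)
  d <- geosphere::distHaversine(cbind(lon[pairs[1, ]], lat[pairs[1, ]]),
                                cbind(lon[pairs[2, ]], lat[pairs[2, ]]),
                                r = 6371)
  expect_equal(mean_conspecific_distance(lat, lon), mean(d))
})

test_that("belt richness standardizes by max (extrapolation) and min (rarefaction)", {
  set.seed(62)
  base <- rand_seq(658)
  haps <- c(base, sub_at(base, 1), sub_at(base, 2), sub_at(base, 3))
  # one species in two belt clusters: n=6 (3 haplotypes) and n=10 (4)
  seqs <- c(haps[c(1, 1, 1, 2, 2, 3)], haps[c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4)])
  lat <- c(rep(40, 6), rep(50, 10))
  lib <- toy_library(species = rep("GenA_sp1", 16), sequences = seqs,
                     latitude = lat, longitude = rep(10, 16))
  belts <- make_belts("latitude", 35, 55, spacing = 5, half_width = 1)
  br <- belt_richness(lib, belts)
  expect_equal(nrow(br), 2L)
  s40 <- br[br$center == 40, ]; s50 <- br[br$center == 50, ]
  # method (i): extrapolate the n=6 belt to m = 10, the species max
  tab40 <- collapse_haplotypes(seqs[1:6])
  expect_equal(s40$richness_extrapolated, standardised_richness(tab40, 10))
  # the belt holding the max is rarefied at its own n: equals S_obs
  expect_equal(s50$richness_extrapolated, 4)
  # method (ii): analytic rarefied richness at m = 6 equals the exhaustive
  # subset mean
  tab50 <- collapse_haplotypes(seqs[7:16])
  expect_equal(s50$richness_subsampled, rarefaction_enum(tab50$abundances, 6),
               tolerance = 1e-9)
  # monomorphic species scores 1 in every belt under both methods
  lib1 <- toy_library(species = rep("GenA_sp1", 12),
                      sequences = rep(base, 12),
                      latitude = c(rep(40, 6), rep(50, 6)),
                      longitude = rep(10, 12))
  br1 <- belt_richness(lib1, belts)
  expect_true(all(br1$richness_extrapolated == 1))
  expect_true(all(br1$richness_subsampled == 1))
})

test_that("proportional duplication changes subsampled richness only slightly", {
  # the analytic rarefied value at fixed m depends on composition and only
  # weakly on total n: replication moves it toward the multinomial limit
  x <- c(4, 3, 2, 1)
  vals <- vapply(c(1, 2, 4, 8), function(f)
    rarefied_richness(x * f, 5), numeric(1))
  # changes shrink geometrically toward the multinomial limit
  steps <- abs(diff(vals))
  expect_true(all(diff(steps) < 0))
  expect_lt(steps[3], 0.05)
  expect_lt(max(vals) - min(vals), 0.35)
})

test_that("a flat response yields no smooth signal and a null distance effect", {
  set.seed(63)
  centers <- seq(35, 55, 0.5)
  richness <- do.call(rbind, lapply(sprintf("sp%d", 1:8), function(s)
    data.frame(center = centers, species = s,
               n = 10, S_obs = 3,
               richness_extrapolated = 3 + rnorm(length(centers), 0, 0.05),
               richness_subsampled = 3,
               mean_km = runif(length(centers), 50, 500))))
  tr <- fit_belt_trend(richness)
  expect_gt(tr$smooth_p, 0.05)
  expect_true(tr$distance_ci[1] < 0 && tr$distance_ci[2] > 0)
})

test_that("loess reproduces polynomials and locates symmetric peaks", {
  x <- seq(0, 10, length.out = 101)
  lin <- loess_curve(x, 2 + 3 * x, span = 0.4)
  expect_lt(max(abs(lin$fit - (2 + 3 * lin$x))), 1e-6)
  # span 1 on quadratic data equals the global quadratic fit
  y <- 1 - 0.5 * x + 0.1 * x^2
  l2 <- loess_curve(x, y, span = 1)
  gq <- lm(y ~ x + I(x^2))
  pred <- predict(gq, newdata = data.frame(x = l2$x))
  expect_lt(max(abs(l2$fit - pred)), 1e-6)
  # symmetric peak recovered within one grid step
  yp <- exp(-(x - 6.2)^2 / 2)
  lp <- loess_curve(x, yp, span = 0.4)
  expect_lt(abs(attr(lp, "argmax") - 6.2), diff(lp$x[1:2]) + 1e-9)
})

test_that("spatial thinning is capped, seeded and idempotent below the cap", {
  set.seed(64)
  lib <- toy_library(species = rep("GenA_sp1", 30),
                     sequences = replicate(30, rand_seq(60)),
                     latitude = c(rep(40.3, 20), runif(10, 50, 55)),
                     longitude = c(rep(7.7, 20), runif(10, 0, 20)), L = 60)
  thin <- spatial_subsample(lib, seed = 1, cell = 1, cap = 5)
  cells <- paste(floor(thin$metadata$latitude), floor(thin$metadata$longitude))
  expect_true(all(table(cells) <= 5))
  expect_equal(sum(thin$metadata$latitude == 40.3), 5L)
  thin2 <- spatial_subsample(lib, seed = 1, cell = 1, cap = 5)
  expect_identical(thin$metadata, thin2$metadata)
  all_kept <- spatial_subsample(lib, seed = 2, cell = 1, cap = 100)
  expect_equal(n_specimens(all_kept), 30L)
})
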