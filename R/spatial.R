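#' Build an overlapping belt grid along latitude or longitude
#'
#' Belt centers form an arithmetic grid from `lo` to `hi` at `spacing`
#' degrees; a specimen belongs to every belt whose center lies within
#' `half_width` degrees of its coordinate (closed boundary), so belts
#' overlap and a specimen typically falls into several.
#'
#' @param axis `"latitude"` or `"longitude"`.
#' @param lo,hi grid extent in decimal degrees (`lo < hi`).
#' @param spacing center spacing (default 0.5).
#' @param half_width half-width of each belt (default 1.0).
#' @return a `belt_grid`: list with `axis`, `centers`, `spacing`,
#'   `half_width`.
#' @export
make_belts <- function(axis = c("latitude", "longitude"), lo, hi,
                       spacing = 0.5, half_width = 1.0) {
  axis <- match.arg(axis)
  stopifnot(lo < hi, spacing > 0, half_width > 0)
  structure(list(axis = axis, centers = seq(lo, hi, by = spacing),
                 spacing = spacing, half_width = half_width),
            class = "belt_grid")
}

#' Belt membership of a coordinate vector
#' @param belts a [make_belts()] grid.
#' @param coords numeric vector of coordinates on the grid's axis.
#' @return list (one element per belt center) of indices into `coords`.
#' @export
belt_members <- function(belts, coords) {
  out <- lapply(belts$centers, function(ctr)
    which(abs(coords - ctr) <= belts$half_width))
  names(out) <- format(belts$centers)
  out
}

#' Mean great-circle distance among conspecific specimens
#'
#' Mean over all pairs of haversine distances (sphere radius 6371 km).
#' Undefined (`NA`) with fewer than two specimens.
#' @param latitude,longitude coordinate vectors (decimal degrees).
#' @return mean pairwise distance in km.
#' @export
mean_conspecific_distance <- function(latitude, longitude) {
  n <- length(latitude)
  if (n < 2L) return(NA_real_)
  pr <- combn(n, 2L)
  d <- geosphere::distHaversine(cbind(longitude[pr[1, ]], latitude[pr[1, ]]),
                                cbind(longitude[pr[2, ]], latitude[pr[2, ]]),
                                r = 6371)
  mean(d)
}

#' Per-belt, per-species standardised haplotype richness
#'
#' For every belt and every species with at least `min_n` specimens in it,
#' computes two sample-size standardisations of haplotype richness:
#' \itemize{
#'   \item `richness_extrapolated` — the rarefaction-extrapolation curve
#'     evaluated at that species' maximum belt sample size across all
#'     belts (method i);
#'   \item `richness_subsampled` — the analytic expected rarefied richness
#'     at the species' minimum qualifying belt sample size (method ii; the
#'     expectation of drawing one random subset of that size).
#' }
#' plus the mean conspecific great-circle distance within the belt.
#'
#' @param lib a `barcode_library`.
#' @param belts a [make_belts()] grid.
#' @param min_n minimum specimens per species per belt (default 6).
#' @param strict haplotype collapsing mode.
#' @return data.frame: center, species, n, S_obs, richness_extrapolated,
#'   richness_subsampled, mean_km.
#' @export
belt_richness <- function(lib, belts, min_n = 6L, strict = FALSE) {
  lib <- species_identified(lib)
  coords <- if (belts$axis == "latitude") lib$metadata$latitude
            else lib$metadata$longitude
  members <- belt_members(belts, coords)
  sp <- lib$metadata$species
  # qualifying belt sample sizes per species
  cells <- list()
  for (b in seq_along(members)) {
    idx <- members[[b]]
    if (!length(idx)) next
    by_sp <- split(idx, sp[idx])
    by_sp <- by_sp[lengths(by_sp) >= min_n]
    for (s in names(by_sp))
      cells[[length(cells) + 1L]] <- list(belt = b, species = s,
                                          idx = by_sp[[s]])
  }
  if (!length(cells))
    return(data.frame(center = numeric(), species = character(),
                      n = integer(), S_obs = integer(),
                      richness_extrapolated = numeric(),
                      richness_subsampled = numeric(),
                      mean_km = numeric(), stringsAsFactors = FALSE))
  ns <- vapply(cells, function(cl) length(cl$idx), integer(1))
  spp <- vapply(cells, function(cl) cl$species, character(1))
  m_max <- tapply(ns, spp, max)
  m_min <- tapply(ns, spp, min)
  rows <- lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    tab <- collapse_haplotypes(lib$sequences[cl$idx], strict = strict)
    data.frame(center = belts$centers[cl$belt], species = cl$species,
               n = tab$n, S_obs = tab$S_obs,
               richness_extrapolated =
                 standardised_richness(tab, m_max[[cl$species]]),
               richness_subsampled =
                 rarefied_richness(tab, m_min[[cl$species]]),
               mean_km = mean_conspecific_distance(
                 lib$metadata$latitude[cl$idx],
                 lib$metadata$longitude[cl$idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-belt means across species
#'
#' Belts with no qualifying species are absent from the output (they carry
#' no information for trend fitting).
#' @param richness output of [belt_richness()].
#' @return data.frame: center, n_species, richness_extrapolated,
#'   richness_subsampled, mean_km (means over species).
#' @export
belt_summary <- function(richness) {
  if (!nrow(richness))
    return(data.frame(center = numeric(), n_species = integer(),
                      richness_extrapolated = numeric(),
                      richness_subsampled = numeric(),
                      mean_km = numeric()))
  agg <- aggregate(cbind(richness_extrapolated, richness_subsampled,
                         mean_km) ~ center, richness, mean,
                   na.action = stats::na.pass)
  cnt <- aggregate(species ~ center, richness, length)
  out <- merge(cnt, agg, by = "center")
  names(out)[names(out) == "species"] <- "n_species"
  out[order(out$center), ]
}

#' Additive-model trend of belt richness along an axis
#'
#' Fits a generalised additive mixed model: richness as response, the belt
#' center as a penalized-spline smooth (basis dimension `k`, default 10),
#' the mean conspecific distance as a parametric (linear) covariate, and a
#' continuous-AR1 (exponential) residual correlation along the axis. In
#' the default per-record mode each species-belt value is one row with a
#' species random intercept; `per_belt = TRUE` instead fits the belt means.
#'
#' @param richness output of [belt_richness()].
#' @param response `"richness_extrapolated"` or `"richness_subsampled"`.
#' @param k smooth basis dimension (reduced automatically when few belts).
#' @param per_belt fit per-belt means instead of species-belt records.
#' @param min_belts minimum number of distinct belts required (default 12).
#' @return list with `fit` (the `gamm` object), `smooth_p`, `smooth_edf`,
#'   `distance_coef`, `distance_se`, `distance_ci`, `aic`, `n`.
#' @export
fit_belt_trend <- function(richness, response = "richness_extrapolated",
                           k = 10, per_belt = FALSE, min_belts = 12L) {
  stopifnot(response %in% names(richness))
  if (per_belt) {
    dat <- belt_summary(richness)
    dat$y <- dat[[response]]
  } else {
    dat <- richness
    dat$y <- dat[[response]]
    dat$species <- factor(dat$species)
  }
  dat <- dat[is.finite(dat$y) & is.finite(dat$mean_km), , drop = FALSE]
  n_belts <- length(unique(dat$center))
  if (n_belts < min_belts)
    stop("need data in at least ", min_belts, " belts, got ", n_belts)
  k_use <- min(k, n_belts - 2L)
  if (per_belt) {
    fit <- mgcv::gamm(y ~ s(center, k = k_use) + mean_km, data = dat,
                      correlation = nlme::corExp(form = ~center))
  } else {
    fit <- mgcv::gamm(y ~ s(center, k = k_use) + mean_km, data = dat,
                      random = list(species = ~1),
                      correlation = nlme::corExp(form = ~center))
  }
  sg <- summary(fit$gam)
  co <- sg$p.table["mean_km", ]
  list(fit = fit,
       smooth_p = unname(sg$s.table[1, "p-value"]),
       smooth_edf = unname(sg$s.table[1, "edf"]),
       distance_coef = unname(co["Estimate"]),
       distance_se = unname(co["Std. Error"]),
       distance_ci = unname(co["Estimate"] +
                              c(-1.96, 1.96) * co["Std. Error"]),
       aic = AIC(fit$lme), n = nrow(dat))
}

#' Loess smooth with pointwise confidence band
#'
#' Tricube-weighted local quadratic regression (span `alpha`), evaluated on
#' a uniform grid with a +/- 1.96 standard-error band.
#'
#' @param x,y numeric vectors (>= 10 points).
#' @param span loess span (default 0.4).
#' @param n_grid grid resolution.
#' @return data.frame: x, fit, se, lower, upper; attribute `argmax` gives
#'   the grid x at which the smooth is maximal.
#' @export
loess_curve <- function(x, y, span = 0.4, n_grid = 200L) {
  stopifnot(length(x) == length(y), length(x) >= 10L)
  fit <- loess(y ~ x, span = span, degree = 2, family = "gaussian",
               surface = "direct")
  grid <- seq(min(x), max(x), length.out = n_grid)
  pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  out <- data.frame(x = grid, fit = pr$fit, se = pr$se.fit,
                    lower = pr$fit - 1.96 * pr$se.fit,
                    upper = pr$fit + 1.96 * pr$se.fit)
  attr(out, "argmax") <- grid[which.max(pr$fit)]
  out
}

#' Seeded spatial thinning to a per-cell specimen cap
#'
#' Overlays a square grid of `cell` degrees and randomly retains at most
#' `cap` specimens per cell, mitigating unequal sampling intensity.
#' Deterministic given `seed`.
#'
#' @param lib a `barcode_library`.
#' @param seed RNG seed.
#' @param cell cell size in degrees (default 1).
#' @param cap maximum specimens retained per cell (default 10).
#' @return a thinned `barcode_library`.
#' @export
spatial_subsample <- function(lib, seed, cell = 1, cap = 10L) {
  set.seed(seed)
  md <- lib$metadata
  cells <- paste(floor(md$latitude / cell), floor(md$longitude / cell))
  keep <- unlist(lapply(split(seq_len(nrow(md)), cells), function(idx) {
    if (length(idx) <= cap) idx else sort(sample(idx, cap))
  }), use.names = FALSE)
  subset_library(lib, sort(keep))
}
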