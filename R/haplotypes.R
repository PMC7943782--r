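#' Collapse one species' sequences into haplotypes
#'
#' Two sequences share a haplotype when they are identical at every position
#' where both carry an unambiguous base (A/C/G/T); grouping is the
#' transitive closure of this pairwise relation, so an N-rich sequence can
#' bridge two otherwise distinct haplotypes. `strict = TRUE` switches to
#' exact string equality over the full frame instead.
#'
#' @param sequences character vector of aligned sequences (one species).
#' @param strict logical; exact full-frame equality instead of
#'   match-on-overlap.
#' @return A `haplotype_table`: list with `n`, `abundances` (descending),
#'   `S_obs`, `f1`, `f2`, and `haplotype` (group index per input sequence).
#' @export
collapse_haplotypes <- function(sequences, strict = FALSE) {
  n <- length(sequences)
  stopifnot(n >= 1L)
  if (strict) {
    grp <- match(sequences, unique(sequences))
  } else {
    chars <- strsplit(toupper(sequences), "", fixed = TRUE)
    L <- unique(lengths(chars))
    stopifnot(length(L) == 1L)
    m <- matrix(match(unlist(chars), DNA_BASES), nrow = n, byrow = TRUE)
    if (!anyNA(m)) # no ambiguity anywhere: overlap rule = exact equality
      return(haplotype_table(sort(tabulate(match(sequences, unique(sequences))),
                                  decreasing = TRUE),
                             haplotype = match(sequences, unique(sequences))))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          both <- !is.na(m[i, ]) & !is.na(m[j, ])
          if (!any(m[i, both] != m[j, both])) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    grp <- match(roots, unique(roots))
  }
  ab <- sort(tabulate(grp), decreasing = TRUE)
  haplotype_table(ab, haplotype = grp)
}

#' Build a haplotype table from an abundance vector
#'
#' @param abundances integer vector, one entry per distinct haplotype
#'   (all >= 1).
#' @param haplotype optional per-specimen group index.
#' @return a `haplotype_table`.
#' @export
haplotype_table <- function(abundances, haplotype = NULL) {
  abundances <- as.integer(abundances)
  stopifnot(length(abundances) >= 1L, all(abundances >= 1L))
  abundances <- sort(abundances, decreasing = TRUE)
  structure(list(n = sum(abundances),
                 abundances = abundances,
                 S_obs = length(abundances),
                 f1 = sum(abundances == 1L),
                 f2 = sum(abundances == 2L),
                 haplotype = haplotype),
            class = "haplotype_table")
}

#' Expected haplotype richness in a rarefied subsample
#'
#' Analytic (hypergeometric) expectation of the number of distinct
#' haplotypes among `m` specimens drawn without replacement:
#' \deqn{S(m) = \sum_i \left[1 - \binom{n - x_i}{m} / \binom{n}{m}\right].}
#'
#' @param table a `haplotype_table` (or abundance vector).
#' @param m subsample size(s), 1 <= m <= n.
#' @return numeric vector of expected richness, one per `m`.
#' @export
rarefied_richness <- function(table, m) {
  x <- as_abundances(table)
  n <- sum(x)
  m <- as.integer(m)
  if (any(m < 1L | m > n)) stop("m must satisfy 1 <= m <= n")
  vapply(m, function(mm) {
    # lchoose(n - x, m) = -Inf when m > n - x, i.e. the haplotype is certain
    sum(1 - exp(lchoose(n - x, mm) - lchoose(n, mm)))
  }, numeric(1))
}

as_abundances <- function(table) {
  if (inherits(table, "haplotype_table")) table$abundances
  else as.integer(table)
}

#' Chao1 asymptotic haplotype richness (bias-corrected)
#'
#' \deqn{\hat S = S_{obs} + \frac{n-1}{n}\,\frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' where f1 and f2 are the numbers of haplotypes observed exactly once and
#' twice. With no singletons the estimate equals the observed richness.
#'
#' @param table a `haplotype_table` or abundance vector.
#' @return estimated asymptotic richness (>= S_obs).
#' @export
chao1_richness <- function(table) {
  x <- as_abundances(table)
  n <- sum(x)
  f1 <- sum(x == 1L); f2 <- sum(x == 2L)
  length(x) + (n - 1) / n * f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Extrapolated haplotype richness beyond the observed sample
#'
#' Expected richness at sample size `n + m_star` under the Chao1 sampling
#' model:
#' \deqn{S(n + m^*) = S_{obs} + \hat f_0 \left[1 - \left(1 -
#'   \frac{f_1}{n \hat f_0 + f_1}\right)^{m^*}\right]}
#' with \eqn{\hat f_0 = \hat S - S_{obs}}. `m_star = 0` returns the observed
#' richness; as `m_star` grows the curve approaches the Chao1 asymptote.
#'
#' @param table a `haplotype_table` or abundance vector.
#' @param m_star integer >= 0, additional specimens.
#' @return expected richness values.
#' @export
extrapolated_richness <- function(table, m_star) {
  x <- as_abundances(table)
  n <- sum(x); S_obs <- length(x); f1 <- sum(x == 1L)
  stopifnot(all(m_star >= 0))
  f0 <- chao1_richness(x) - S_obs
  if (f0 == 0 || f1 == 0) return(rep(S_obs, length(m_star)))
  S_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m_star)
}

#' Richness standardised to an arbitrary sample size
#'
#' Dispatches to analytic rarefaction for `m <= n` and to Chao1
#' extrapolation for `m > n`, giving the continuous
#' rarefaction-extrapolation curve through the observed point.
#' @param table a `haplotype_table` or abundance vector.
#' @param m target sample size(s), >= 1.
#' @return numeric vector.
#' @export
standardised_richness <- function(table, m) {
  x <- as_abundances(table)
  n <- sum(x)
  out <- numeric(length(m))
  lo <- m <= n
  if (any(lo)) out[lo] <- rarefied_richness(x, m[lo])
  if (any(!lo)) out[!lo] <- extrapolated_richness(x, m[!lo] - n)
  out
}

#' Sampling completeness of a species' haplotype inventory
#'
#' Observed over Chao1-estimated asymptotic richness. Following the library
#' inclusion rule for this analysis, species sampled with fewer than
#' `min_n` specimens are excluded (`included = FALSE`) rather than erroring.
#'
#' @param table a `haplotype_table` or abundance vector.
#' @param min_n minimum sample size for inclusion (default 6).
#' @return list with `S_obs`, `S_hat`, `completeness` in (0, 1], `n`,
#'   `included`.
#' @export
sampling_completeness <- function(table, min_n = 6L) {
  x <- as_abundances(table)
  n <- sum(x)
  S_hat <- chao1_richness(x)
  list(n = n, S_obs = length(x), S_hat = S_hat,
       completeness = length(x) / S_hat,
       included = n >= min_n)
}

#' Per-species diversity summary for a whole library
#'
#' Collapses haplotypes per species and reports observed richness, Chao1
#' asymptote and completeness; the cohort is restricted to species with at
#' least `min_n` specimens.
#'
#' @param lib a `barcode_library`.
#' @param min_n inclusion threshold (default 6).
#' @param strict haplotype collapsing mode, see [collapse_haplotypes()].
#' @return data.frame: species, n, S_obs, S_hat, completeness, included.
#' @export
diversity_summary <- function(lib, min_n = 6L, strict = FALSE) {
  lib <- species_identified(lib)
  split_idx <- split(seq_len(n_specimens(lib)), lib$metadata$species)
  rows <- lapply(names(split_idx), function(sp) {
    tab <- collapse_haplotypes(lib$sequences[split_idx[[sp]]], strict = strict)
    cpl <- sampling_completeness(tab, min_n = min_n)
    data.frame(species = sp, n = cpl$n, S_obs = cpl$S_obs, S_hat = cpl$S_hat,
               completeness = cpl$completeness, included = cpl$included,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

OCTAVE_LABELS <- c("1", "2-3", "4-7", "8-15", "16-31", "32-63",
                   "64-127", "128-255")

#' Octave (log2 abundance class) profile of haplotype frequencies
#'
#' Haplotype abundances are binned into the eight geometric classes
#' 1, 2–3, 4–7, 8–15, 16–31, 32–63, 64–127, 128–255; per species the
#' relative frequency of haplotypes in each class is computed, then the
#' cross-species mean and standard deviation per class. Abundances above
#' 255 are clamped into the top class with a warning, keeping the
#' eight-class contract.
#'
#' @param tables a list of `haplotype_table`s (or abundance vectors), one
#'   per species.
#' @return list with `classes` (labels), `per_species` (species x 8 matrix
#'   of relative frequencies), `mean`, `sd` (per-class, across species).
#' @export
octave_profile <- function(tables) {
  stopifnot(length(tables) >= 1L)
  freq <- t(vapply(tables, function(tab) {
    x <- as_abundances(tab)
    cls <- floor(log2(x)) + 1L
    if (any(cls > 8L)) {
      warning("abundance >= 256 clamped into class 128-255")
      cls[cls > 8L] <- 8L
    }
    tabulate(cls, nbins = 8L) / length(x)
  }, numeric(8)))
  colnames(freq) <- OCTAVE_LABELS
  list(classes = OCTAVE_LABELS,
       per_species = freq,
       mean = colMeans(freq),
       sd = apply(freq, 2, sd))
}
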