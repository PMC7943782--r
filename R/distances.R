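#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: positions where either sequence is not an unambiguous
#' base (A/C/G/T) are dropped; `p` is the proportion of the remaining
#' compared sites that differ. Pairs with fewer than `min_overlap` compared
#' sites are flagged invalid and excluded from downstream summaries.
#'
#' @param a,b aligned sequences (equal length).
#' @param min_overlap minimum number of compared sites for a valid pair
#'   (default 300, half the standard barcode).
#' @return list with `compared_sites`, `differences`, `p`, `valid`.
#' @export
p_distance <- function(a, b, min_overlap = 300L) {
  ca <- match(strsplit(toupper(a), "")[[1]], DNA_BASES)
  cb <- match(strsplit(toupper(b), "")[[1]], DNA_BASES)
  stopifnot(length(ca) == length(cb))
  both <- !is.na(ca) & !is.na(cb)
  compared <- sum(both)
  diffs <- sum(ca[both] != cb[both])
  list(compared_sites = compared, differences = diffs,
       p = if (compared > 0) diffs / compared else NA_real_,
       valid = compared >= min_overlap)
}

#' All pairwise p-distances of a library
#'
#' Computes the full symmetric matrix of uncorrected p-distances with
#' pairwise deletion via base-indicator cross-products (no per-pair loops).
#' Entries for invalid pairs (overlap below `min_overlap`) are `NA`.
#'
#' @param lib a `barcode_library`.
#' @param min_overlap minimum compared sites per valid pair.
#' @return list with matrices `p`, `compared`, `differences` (specimen ids
#'   as dimnames).
#' @export
p_distance_matrix <- function(lib, min_overlap = 300L) {
  m <- sequence_matrix(lib)
  valid <- !is.na(m)
  storage.mode(valid) <- "double"
  compared <- tcrossprod(valid)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    ind <- valid * (m == b)
    ind[is.na(ind)] <- 0
    matches <- matches + tcrossprod(ind)
  }
  diffs <- compared - matches
  p <- diffs / compared
  p[compared < min_overlap] <- NA_real_
  ids <- lib$metadata$specimen_id
  dimnames(p) <- dimnames(compared) <- dimnames(diffs) <- list(ids, ids)
  list(p = p, compared = compared, differences = diffs)
}

#' Per-species distance summaries and nearest neighbours
#'
#' For every species with identified records: mean and maximum
#' intraspecific p-distance (undefined for singletons) and the
#' nearest-neighbour distance — the minimum p-distance from any of its
#' specimens to any specimen of any other species. Ties for nearest
#' neighbour are all listed, separated by `|`.
#'
#' Distances are proportions (full precision); multiply by 100 for the
#' percentages conventionally reported.
#'
#' @param lib a `barcode_library` (genus-level records are dropped).
#' @param dm optional precomputed [p_distance_matrix()] of
#'   `species_identified(lib)`.
#' @param min_overlap passed to [p_distance_matrix()].
#' @return data.frame: species, n, mean_intra, max_intra, nn_species,
#'   nn_dist.
#' @export
species_distance_summary <- function(lib, dm = NULL, min_overlap = 300L) {
  lib <- species_identified(lib)
  if (is.null(dm)) dm <- p_distance_matrix(lib, min_overlap = min_overlap)
  p <- dm$p
  sp <- lib$metadata$species
  species <- sort(unique(sp))
  rows <- lapply(species, function(s) {
    own <- which(sp == s)
    other <- which(sp != s)
    intra <- p[own, own, drop = FALSE][upper.tri(matrix(0, length(own), length(own)))]
    intra <- intra[!is.na(intra)]
    inter <- p[own, other, drop = FALSE]
    ok <- !is.na(inter)
    if (any(ok)) {
      nn_dist <- min(inter[ok])
      hit <- which(inter == nn_dist & ok, arr.ind = TRUE)
      nn_species <- paste(sort(unique(sp[other][hit[, 2]])), collapse = "|")
    } else {
      nn_dist <- NA_real_; nn_species <- NA_character_
    }
    data.frame(species = s, n = length(own),
               mean_intra = if (length(intra)) mean(intra) else NA_real_,
               max_intra = if (length(intra)) max(intra) else NA_real_,
               nn_species = nn_species, nn_dist = nn_dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect cases of barcode sharing between species
#'
#' Builds a graph over species with an edge whenever some cross-species
#' specimen pair has p-distance exactly zero; each connected component of
#' two or more species is one sharing case. Reports, per case, the species
#' involved and the number of specimens of each that participate in a
#' zero-distance link, plus the component size distribution
#' (pairs / triplets / ...).
#'
#' @param lib a `barcode_library`.
#' @param dm optional precomputed [p_distance_matrix()] of
#'   `species_identified(lib)`.
#' @param min_overlap passed to [p_distance_matrix()].
#' @return list with `cases` (data.frame case/species/n_specimens_involved),
#'   `n_cases`, `size_distribution` (table over component sizes),
#'   `species_involved`.
#' @export
detect_barcode_sharing <- function(lib, dm = NULL, min_overlap = 300L) {
  lib <- species_identified(lib)
  if (is.null(dm)) dm <- p_distance_matrix(lib, min_overlap = min_overlap)
  sp <- lib$metadata$species
  zero <- which(dm$p == 0 & outer(sp, sp, "!="), arr.ind = TRUE)
  empty <- data.frame(case = integer(), species = character(),
                      n_specimens_involved = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(zero) == 0L)
    return(list(cases = empty, n_cases = 0L,
                size_distribution = table(integer()),
                species_involved = character()))
  edges <- unique(data.frame(a = pmin(sp[zero[, 1]], sp[zero[, 2]]),
                             b = pmax(sp[zero[, 1]], sp[zero[, 2]]),
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  involved_specimens <- unique(c(zero[, 1], zero[, 2]))
  cases <- do.call(rbind, lapply(seq_len(comp$no), function(k) {
    spp <- sort(names(membership)[membership == k])
    data.frame(case = k, species = spp,
               n_specimens_involved = vapply(spp, function(s)
                 sum(sp[involved_specimens] == s), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(cases) <- NULL
  list(cases = cases, n_cases = comp$no,
       size_distribution = table(comp$csize),
       species_involved = sort(names(membership)))
}

#' Flag taxa needing taxonomic attention from distance summaries
#'
#' Three audit flags per species: `deep_split` when the maximum
#' intraspecific p-distance exceeds `deep_threshold` (candidate cryptic
#' diversity), `shared` when the nearest-neighbour distance is exactly
#' zero (barcode sharing), and `low_divergence` when the nearest-neighbour
#' distance is positive but below `low_nn_threshold`. Thresholds are in
#' percent; comparisons are strict.
#'
#' @param summaries output of [species_distance_summary()].
#' @param deep_threshold percent, default 2.5.
#' @param low_nn_threshold percent, default 0.61 (4 substitutions over the
#'   658-site frame).
#' @return `summaries` with logical columns `deep_split`, `shared`,
#'   `low_divergence` appended.
#' @export
flag_taxa <- function(summaries, deep_threshold = 2.5,
                      low_nn_threshold = 0.61) {
  deep <- deep_threshold / 100
  low <- low_nn_threshold / 100
  summaries$deep_split <- !is.na(summaries$max_intra) &
    summaries$max_intra > deep
  summaries$shared <- !is.na(summaries$nn_dist) & summaries$nn_dist == 0
  summaries$low_divergence <- !is.na(summaries$nn_dist) &
    summaries$nn_dist > 0 & summaries$nn_dist < low
  summaries
}
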