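# Small in-code fixtures and independent oracles shared across tests.

# Random aligned sequence of length L
rand_seq <- function(L = 658L) paste(sample(c("A", "C", "G", "T"), L,
                                            replace = TRUE), collapse = "")

# Substitute the bases at `positions` of `seq` deterministically (A->C,
# C->G, G->T, T->A), guaranteeing a difference.
sub_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

# Minimal hand-built library: `spec` is a data.frame with columns species
# (and optionally genus/subfamily/family, lat, lon) plus a list of
# sequences per row.
toy_library <- function(species, sequences, genus = NULL, subfamily = NULL,
                        family = NULL, latitude = NULL, longitude = NULL,
                        L = nchar(sequences[1])) {
  n <- length(sequences)
  if (is.null(genus)) genus <- sub("_.*$", "", ifelse(species == "",
                                                      "GenX", species))
  if (is.null(subfamily)) subfamily <- rep("SubA", n)
  if (is.null(family)) family <- rep("FamA", n)
  md <- data.frame(specimen_id = sprintf("sp%03d", seq_len(n)),
                   family = family, subfamily = subfamily, genus = genus,
                   species = species,
                   latitude = latitude %||% rep(45, n),
                   longitude = longitude %||% rep(10, n),
                   stringsAsFactors = FALSE)
  barcode_library(md, stats::setNames(sequences, md$specimen_id), L = L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# Exhaustive rarefaction: mean number of distinct haplotype labels over all
# C(n, m) subsets of the specimen pool implied by an abundance vector.
rarefaction_enum <- function(abundances, m) {
  labels <- rep(seq_along(abundances), abundances)
  subs <- utils::combn(length(labels), m)
  mean(apply(subs, 2, function(ix) length(unique(labels[ix]))))
}

# All integer partitions of n (decreasing parts).
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - p, p)) out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# Union-find connected components over a species zero-distance edge list.
union_find_components <- function(vertices, edges_a, edges_b) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(v) { while (parent[[v]] != v) v <- parent[[v]]; v }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(vertices, find, character(1))
  split(vertices, roots)
}

# Brute-force p-distance between two sequences (independent of the
# package's vectorised implementation).
p_dist_brute <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[ok] != cb[ok]) / sum(ok)
}
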