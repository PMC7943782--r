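#' @importFrom stats sd aggregate median rnorm runif pt predict loess dnorm rmultinom AIC
#' @importFrom utils read.delim write.csv write.table combn head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Metadata columns of a barcode reference library
#'
#' Fixed TSV header used by [read_barcode_library()] and
#' [write_barcode_library()]. Species is the empty string for specimens
#' identified only to genus level.
#' @export
LIBRARY_COLUMNS <- c("specimen_id", "family", "subfamily", "genus",
                     "species", "latitude", "longitude")

#' Construct a barcode reference library
#'
#' A library bundles a specimen metadata table with aligned COI sequences in
#' a fixed coordinate frame of length `L`. Sequences use the alphabet
#' A/C/G/T/N/- (ambiguity codes other than N are not supported); all must
#' have exactly `L` characters.
#'
#' @param metadata data.frame with the columns in [LIBRARY_COLUMNS].
#' @param sequences named character vector of aligned sequences; names must
#'   match `metadata$specimen_id` one-to-one.
#' @param L alignment length (default 658, the standard COI barcode frame).
#' @return An object of class `barcode_library` with elements `metadata`,
#'   `sequences`, `L`.
#' @export
barcode_library <- function(metadata, sequences, L = 658L) {
  stopifnot(is.data.frame(metadata))
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  metadata <- metadata[, LIBRARY_COLUMNS]
  metadata$specimen_id <- as.character(metadata$specimen_id)
  for (col in c("family", "subfamily", "genus", "species")) {
    metadata[[col]] <- as.character(metadata[[col]])
    metadata[[col]][is.na(metadata[[col]])] <- ""
  }
  if (anyDuplicated(metadata$specimen_id))
    stop("duplicate specimen_id in metadata")
  sequences <- toupper(as.character(sequences))
  if (is.null(names(sequences)) && length(sequences) == nrow(metadata))
    names(sequences) <- metadata$specimen_id
  if (!setequal(names(sequences), metadata$specimen_id))
    stop("sequence names do not match metadata specimen ids")
  sequences <- sequences[metadata$specimen_id]
  bad_len <- nchar(sequences) != L
  if (any(bad_len))
    stop(sum(bad_len), " sequence(s) are not of alignment length L = ", L)
  bad_char <- grepl("[^ACGTN-]", sequences)
  if (any(bad_char))
    stop("sequences contain characters outside {A,C,G,T,N,-}")
  structure(list(metadata = metadata, sequences = sequences, L = as.integer(L)),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  sp <- species_identified(x)
  cat("barcode_library:", nrow(x$metadata), "specimens,",
      length(unique(sp$metadata$species)), "species, L =", x$L, "\n")
  invisible(x)
}

#' Number of specimens in a library
#' @param lib a `barcode_library`.
#' @return integer count.
#' @export
n_specimens <- function(lib) nrow(lib$metadata)

#' Subset a library to the species-identified records
#'
#' Records with an empty species field (identified to genus only) are
#' dropped.
#' @param lib a `barcode_library`.
#' @return a `barcode_library`.
#' @export
species_identified <- function(lib) {
  keep <- lib$metadata$species != ""
  subset_library(lib, keep)
}

#' Subset a library by a logical or index vector
#' @param lib a `barcode_library`.
#' @param idx logical or integer index over specimens.
#' @return a `barcode_library`.
#' @export
subset_library <- function(lib, idx) {
  md <- lib$metadata[idx, , drop = FALSE]
  rownames(md) <- NULL
  barcode_library(md, lib$sequences[md$specimen_id], lib$L)
}

#' Count unambiguous (A/C/G/T) positions per sequence
#' @param sequences character vector of sequences.
#' @return integer vector.
#' @export
informative_sites <- function(sequences) {
  nchar(gsub("[^ACGT]", "", toupper(sequences)))
}

# Integer encoding of the aligned sequences: n x L matrix, 1..4 for
# A/C/G/T, NA for N and gaps. The workhorse representation for all distance
# and haplotype computations.
sequence_matrix <- function(lib) {
  chars <- strsplit(lib$sequences, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), DNA_BASES),
              nrow = n_specimens(lib), ncol = lib$L, byrow = TRUE)
  rownames(m) <- lib$metadata$specimen_id
  m
}

#' Read a barcode reference library from FASTA plus metadata TSV
#'
#' Sequences are read with Biostrings; ids must resolve one-to-one against
#' the metadata table. Records with fewer than `min_sites` unambiguous
#' (A/C/G/T) positions are excluded from the library and counted — the
#' standard "at least 600 bp" inclusion rule for reference barcodes.
#' Records with unparseable coordinates are kept but flagged.
#'
#' @param fasta path to a FASTA file of aligned sequences.
#' @param metadata path to a TSV with the columns in [LIBRARY_COLUMNS], or a
#'   data.frame.
#' @param L alignment length.
#' @param min_sites minimum number of unambiguous positions (default 600).
#' @return list with `library` (a `barcode_library`), `n_excluded`,
#'   `excluded_ids` and `invalid_coordinate_ids`.
#' @export
read_barcode_library <- function(fasta, metadata, L = 658L, min_sites = 600L) {
  seqs_raw <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs_raw) == 0L) warning("empty FASTA: ", fasta)
  seqs <- toupper(as.character(seqs_raw))
  names(seqs) <- sub("\\s.*$", "", names(seqs_raw))
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids in FASTA")
  if (is.character(metadata))
    metadata <- read.delim(metadata, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  md <- as.data.frame(metadata, stringsAsFactors = FALSE)
  missing_md <- setdiff(names(seqs), md$specimen_id)
  if (length(missing_md))
    stop("FASTA ids absent from metadata: ",
         paste(head(missing_md, 5), collapse = ", "))
  md <- md[match(names(seqs), md$specimen_id), , drop = FALSE]
  lat <- suppressWarnings(as.numeric(md$latitude))
  lon <- suppressWarnings(as.numeric(md$longitude))
  invalid_coord <- is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180
  md$latitude <- lat
  md$longitude <- lon
  keep <- informative_sites(seqs) >= min_sites
  lib <- barcode_library(md[keep, , drop = FALSE], seqs[keep], L = L)
  list(library = lib,
       n_excluded = sum(!keep),
       excluded_ids = names(seqs)[!keep],
       invalid_coordinate_ids = md$specimen_id[invalid_coord & keep])
}

#' Write a library to FASTA + TSV
#'
#' The TSV dialect is fixed (UTF-8, tab separated, header row, empty string
#' for missing species) so that a write/read round trip reproduces the
#' records exactly.
#' @param lib a `barcode_library`.
#' @param fasta,tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_barcode_library <- function(lib, fasta, tsv) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(lib$sequences), fasta, width = 80L)
  write.table(lib$metadata, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Validate the taxonomic hierarchy of a library
#'
#' Checks that the 4-level taxonomy (family / subfamily / genus / species)
#' is hierarchically consistent: each genus under exactly one subfamily,
#' each subfamily under exactly one family, each species under exactly one
#' genus. Reports taxon counts per level and all violations.
#'
#' @param lib a `barcode_library`.
#' @return list with `counts` (named integer vector), `violations`
#'   (data.frame level/taxon/parents), `n_species_identified`,
#'   `n_genus_level`.
#' @export
validate_taxonomy <- function(lib) {
  md <- lib$metadata
  sp_md <- md[md$species != "", , drop = FALSE]
  check_level <- function(child, parent, level) {
    tab <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
    multi <- names(which(table(tab$child) > 1))
    if (!length(multi)) return(NULL)
    data.frame(level = level, taxon = multi,
               parents = vapply(multi, function(g)
                 paste(sort(tab$parent[tab$child == g]), collapse = "|"), ""),
               stringsAsFactors = FALSE)
  }
  violations <- rbind(
    check_level(md$subfamily, md$family, "subfamily"),
    check_level(md$genus, md$subfamily, "genus"),
    check_level(paste(sp_md$genus, sp_md$species), sp_md$genus, "species"))
  if (is.null(violations))
    violations <- data.frame(level = character(), taxon = character(),
                             parents = character(), stringsAsFactors = FALSE)
  list(counts = c(families = length(unique(md$family)),
                  subfamilies = length(unique(md$subfamily)),
                  genera = length(unique(md$genus)),
                  species = length(unique(sp_md$species))),
       violations = violations,
       n_species_identified = nrow(sp_md),
       n_genus_level = nrow(md) - nrow(sp_md))
}

#' Read a species-level phylogeny and match it to a library
#'
#' Reads a single rooted Newick tree with `ape`, reports tips not present in
#' the library (and vice versa), and warns when the tree is not ultrametric
#' (the Pagel lambda transform remains defined either way).
#'
#' @param path Newick file.
#' @param species optional character vector of species names to match
#'   against (e.g. `unique(lib$metadata$species)`); if `NULL`, no matching.
#' @return list with `tree` (an `ape::phylo`), `unmatched_tips`,
#'   `missing_species`.
#' @export
read_species_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed Newick file: ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree")
  if (!ape::is.ultrametric(tree, option = 2))
    warning("tree is not ultrametric")
  unmatched <- character()
  missing <- character()
  if (!is.null(species)) {
    species <- setdiff(unique(species), "")
    unmatched <- setdiff(tree$tip.label, species)
    missing <- setdiff(species, tree$tip.label)
  }
  list(tree = tree, unmatched_tips = unmatched, missing_species = missing)
}
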