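#' Configuration for the synthetic barcode-library generator
#'
#' Defaults describe a desk-scale library with the statistical shape of a
#' curated continental COI dataset: a 4-level taxonomy, singleton-dominated
#' geometric haplotype abundance profiles, specimen counts that grow with
#' range size (mean about 48 specimens per species), and a latitudinal
#' richness gradient peaking in the southern-refugium belt.
#'
#' @param seed integer RNG seed; the whole dataset is deterministic given
#'   the seed.
#' @param n_families,subfamilies_per_family,genera_per_subfamily,species_per_genus
#'   taxonomy dimensions (all >= 1).
#' @param L barcode alignment length.
#' @param species_divergence substitutions placed on each congeneric
#'   species' private block; congeners differ by at least this many sites.
#' @param haplotype_shape geometric abundance parameter in (0, 1); weight of
#'   haplotype k is `haplotype_shape^(k-1)` (renormalised).
#' @param range_richness_slope exponent linking range size to the true
#'   haplotype count, `K ~ richness_coef * range^slope` (log-normal noise
#'   `richness_log_sd`).
#' @param richness_coef,richness_log_sd scale and log-sd of the
#'   range-to-richness law.
#' @param lat_gradient `NULL`, or list(peak, sd, base): haplotype
#'   availability at latitude x scales with
#'   `base + (1-base) * exp(-(x-peak)^2 / (2 sd^2))`, producing a peaked
#'   latitudinal richness gradient.
#' @param lat_range,lon_range study extent in decimal degrees.
#' @param specimen_coef,specimen_exponent,specimen_log_sd specimen count
#'   per species, `max(1, round(coef * range^exponent * e))` with
#'   log-normal sampling-effort noise `e` (log-sd `specimen_log_sd`), so
#'   effort is correlated with — but not a deterministic function of —
#'   range size.
#' @param n_specimens_fixed optional fixed specimen count per species,
#'   overriding the range law.
#' @param range_bounds log-uniform range-size draw bounds (occupied cells).
#' @param introgression_pairs list of `list(donor=, recipient=, n=)`:
#'   exactly `n` specimens of the recipient species carry a barcode
#'   identical to the donor's most common haplotype.
#' @return a `barcode_sim_config` list.
#' @export
barcode_sim_config <- function(seed = 1L,
                               n_families = 3L,
                               subfamilies_per_family = 2L,
                               genera_per_subfamily = 3L,
                               species_per_genus = 3L,
                               L = 658L,
                               species_divergence = 10L,
                               haplotype_shape = 0.9,
                               range_richness_slope = 0.125,
                               richness_coef = 30,
                               richness_log_sd = 0.5,
                               lat_gradient = list(peak = 42.5, sd = 5,
                                                   base = 0.2),
                               lat_range = c(35, 70),
                               lon_range = c(-9, 36),
                               specimen_coef = 1.7,
                               specimen_exponent = 0.5,
                               specimen_log_sd = 0.4,
                               n_specimens_fixed = NULL,
                               range_bounds = c(10, 1e4),
                               introgression_pairs = list()) {
  cfg <- as.list(environment())
  stopifnot(n_families >= 1, subfamilies_per_family >= 1,
            genera_per_subfamily >= 1, species_per_genus >= 1,
            haplotype_shape > 0, haplotype_shape < 1,
            species_divergence >= 1, L >= 1)
  class(cfg) <- "barcode_sim_config"
  cfg
}

#' Multinomial haplotype abundances under geometric weights
#'
#' Draws `n` specimens over `K` haplotype labels whose sampling weights
#' decay geometrically, `shape^(k-1)` (renormalised). Zero realised
#' abundances are allowed — unobserved haplotypes are exactly what makes
#' sampling completeness fall below one.
#'
#' @param shape geometric parameter in (0, 1).
#' @param K number of haplotype labels (>= 1).
#' @param n number of specimens (>= 1).
#' @return integer vector of length `K` summing to `n`.
#' @export
sample_abundances <- function(shape, K, n) {
  stopifnot(K >= 1, n >= 1, shape > 0, shape < 1)
  w <- shape^(seq_len(K) - 1)
  as.integer(stats::rmultinom(1, n, w / sum(w)))
}

gradient_value <- function(x, gradient) {
  gradient$base + (1 - gradient$base) *
    exp(-(x - gradient$peak)^2 / (2 * gradient$sd^2))
}

mutate_at <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

#' Generate a synthetic barcode reference library with known truth
#'
#' Builds a 4-level taxonomy, per-genus ancestral barcodes, congeneric
#' species separated by private substitution blocks, per-species haplotype
#' sets (pairwise distinct, geometric abundance weights), specimen counts
#' and geographic ranges tied to a log-uniform range size, an optional
#' latitudinal gradient in locally available haplotype richness, optional
#' cross-species barcode sharing (introgression), and a taxonomy-consistent
#' ultrametric tree. Deterministic given `cfg$seed`.
#'
#' @param cfg a [barcode_sim_config()].
#' @return list with `library` (a `barcode_library`), `truth` (data.frame:
#'   species, true_haplotype_count, true_range_size plus list-columns of
#'   haplotype sequences and probabilities), `tree` (`ape::phylo`,
#'   ultrametric), `ranges` (data.frame species/range_size).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "barcode_sim_config"))
  set.seed(cfg$seed)
  n_genera <- cfg$n_families * cfg$subfamilies_per_family *
    cfg$genera_per_subfamily
  n_species <- n_genera * cfg$species_per_genus

  taxa <- expand.grid(sp = seq_len(cfg$species_per_genus),
                      gen = seq_len(cfg$genera_per_subfamily),
                      sub = seq_len(cfg$subfamilies_per_family),
                      fam = seq_len(cfg$n_families))
  fam_id <- taxa$fam
  sub_id <- (taxa$fam - 1) * cfg$subfamilies_per_family + taxa$sub
  gen_id <- (sub_id - 1) * cfg$genera_per_subfamily + taxa$gen
  species <- sprintf("Gen%02d_sp%d", gen_id, taxa$sp)
  family <- sprintf("Fam%d", fam_id)
  subfamily <- sprintf("Fam%d_Sub%d", fam_id, (sub_id - 1) %%
                         cfg$subfamilies_per_family + 1)
  genus <- sprintf("Gen%02d", gen_id)

  # range size, specimen count, true haplotype richness
  range_size <- exp(runif(n_species, log(cfg$range_bounds[1]),
                          log(cfg$range_bounds[2])))
  n_spec <- if (!is.null(cfg$n_specimens_fixed))
    rep(as.integer(cfg$n_specimens_fixed), length.out = n_species)
  else
    pmax(1L, as.integer(round(cfg$specimen_coef *
                                range_size^cfg$specimen_exponent *
                                exp(rnorm(n_species, 0,
                                          cfg$specimen_log_sd)))))
  K <- pmax(1L, as.integer(round(
    cfg$richness_coef * range_size^cfg$range_richness_slope *
      exp(rnorm(n_species, 0, cfg$richness_log_sd)))))

  block_need <- cfg$species_per_genus * cfg$species_divergence
  depth_need <- floor((max(K) - 1) / 4)
  if (block_need + max(K) + depth_need > cfg$L)
    stop("infeasible config: required haplotypes exceed sequence space")

  # per-genus ancestral barcode; per-species private substitution block
  genus_names <- sprintf("Gen%02d", seq_len(n_genera))
  ancestors <- lapply(genus_names, function(g)
    sample(DNA_BASES, cfg$L, replace = TRUE))
  names(ancestors) <- genus_names

  hap_seqs <- vector("list", n_species)
  hap_prob <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    anc <- ancestors[[genus[s]]]
    slot <- (s - 1) %% cfg$species_per_genus # block index within genus
    block <- slot * cfg$species_divergence + seq_len(cfg$species_divergence)
    base_seq <- mutate_at(anc, block)
    # haplotype k: one private substitution plus floor((k-1)/4) shared
    # "depth" substitutions, so rarer haplotypes sit further from the core
    # (mean intraspecific divergence a few tenths of a percent, rising
    # with true richness)
    hap_positions <- block_need + seq_len(K[s]) # outside all congener blocks
    depth_pool <- block_need + K[s] + seq_len(max(0L, floor((K[s] - 1) / 4)))
    depth_seq <- mutate_at(base_seq, depth_pool) # fixed variant per position
    seqs <- character(K[s])
    seqs[1] <- paste(base_seq, collapse = "")
    if (K[s] > 1) {
      for (k in 2:K[s]) {
        hk <- mutate_at(base_seq, hap_positions[k])
        e_k <- floor((k - 1) / 4)
        if (e_k > 0) hk[depth_pool[seq_len(e_k)]] <-
            depth_seq[depth_pool[seq_len(e_k)]]
        seqs[k] <- paste(hk, collapse = "")
      }
    }
    hap_seqs[[s]] <- seqs
    w <- cfg$haplotype_shape^(seq_len(K[s]) - 1)
    hap_prob[[s]] <- w / sum(w)
  }

  # geographic ranges: latitudinal interval widening with range size
  lat_lo <- cfg$lat_range[1]; lat_hi <- cfg$lat_range[2]
  width <- pmin(lat_hi - lat_lo,
                5 + 25 * (log10(range_size) - log10(cfg$range_bounds[1])) /
                  max(1e-9, log10(cfg$range_bounds[2] / cfg$range_bounds[1])))
  center <- runif(n_species, lat_lo + width / 2, pmax(lat_lo + width / 2,
                                                      lat_hi - width / 2))
  lon_lo <- cfg$lon_range[1]; lon_hi <- cfg$lon_range[2]

  md_list <- vector("list", n_species)
  seq_list <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    n_s <- n_spec[s]
    lat <- runif(n_s, center[s] - width[s] / 2, center[s] + width[s] / 2)
    lat <- pmin(lat_hi, pmax(lat_lo, lat))
    lon <- runif(n_s, lon_lo, lon_hi)
    if (is.null(cfg$lat_gradient)) {
      ab <- sample_abundances(cfg$haplotype_shape, K[s], n_s)
      hap_idx <- rep(seq_len(K[s]), ab)
    } else {
      k_eff <- pmax(1L, as.integer(ceiling(
        K[s] * gradient_value(lat, cfg$lat_gradient))))
      hap_idx <- vapply(k_eff, function(ke) {
        w <- hap_prob[[s]][seq_len(ke)]
        sample.int(ke, 1L, prob = w / sum(w))
      }, integer(1))
    }
    md_list[[s]] <- data.frame(
      specimen_id = sprintf("%s_%04d", species[s], seq_len(n_s)),
      family = family[s], subfamily = subfamily[s], genus = genus[s],
      species = species[s], latitude = lat, longitude = lon,
      stringsAsFactors = FALSE)
    seq_list[[s]] <- hap_seqs[[s]][hap_idx]
  }
  md <- do.call(rbind, md_list)
  seqs <- unlist(seq_list)
  names(seqs) <- md$specimen_id

  # introgression: recipient specimens carry the donor's commonest
  # haplotype; one donor specimen is pinned to that haplotype so the shared
  # barcode is guaranteed to be present on both sides of the pair
  for (pair in cfg$introgression_pairs) {
    donor <- match(pair$donor, species)
    recip <- which(md$species == pair$recipient)
    if (is.na(donor) || length(recip) < pair$n)
      stop("invalid introgression pair: ", pair$donor, " -> ",
           pair$recipient)
    seqs[which(md$species == pair$donor)[1]] <- hap_seqs[[donor]][1]
    take <- sample(recip, pair$n)
    seqs[take] <- hap_seqs[[donor]][1]
  }

  lib <- barcode_library(md, seqs, L = cfg$L)
  truth <- data.frame(species = species,
                      true_haplotype_count = K,
                      true_range_size = range_size,
                      stringsAsFactors = FALSE)
  truth$haplotype_sequences <- hap_seqs
  truth$haplotype_probabilities <- hap_prob
  tree <- taxonomy_cladogram(family, subfamily, genus, species)
  list(library = lib, truth = truth, tree = tree,
       ranges = data.frame(species = species, range_size = range_size,
                           stringsAsFactors = FALSE))
}

# Ultrametric cladogram consistent with the 4-level taxonomy: unit branch
# per rank (species tips at depth 4 from the root). Single-child groups are
# collapsed by absorbing the rank's branch length into the child, keeping
# the tree ultrametric without unifurcations.
taxonomy_cladogram <- function(family, subfamily, genus, species) {
  tab <- unique(data.frame(family, subfamily, genus, species,
                           stringsAsFactors = FALSE))
  add_bl <- function(str, bl) {
    old <- as.numeric(sub("^.*:([0-9.]+)$", "\\1", str))
    sub(":[0-9.]+$", paste0(":", old + bl), str)
  }
  join <- function(children, bl) {
    if (length(children) == 1L) add_bl(children, bl)
    else paste0("(", paste(children, collapse = ","), "):", bl)
  }
  fam_strs <- vapply(unique(tab$family), function(f) {
    subs <- unique(tab$subfamily[tab$family == f])
    sub_strs <- vapply(subs, function(sb) {
      gens <- unique(tab$genus[tab$subfamily == sb])
      gen_strs <- vapply(gens, function(g)
        join(paste0(tab$species[tab$genus == g], ":1"), 1), character(1))
      join(gen_strs, 1)
    }, character(1))
    join(sub_strs, 1)
  }, character(1))
  newick <- if (length(fam_strs) == 1L)
    paste0(sub(":[0-9.]+$", "", fam_strs), ";")
  else paste0("(", paste(fam_strs, collapse = ","), ");")
  ape::read.tree(text = newick)
}

#' Write a synthetic dataset to disk in the library's standard formats
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "library.fasta"),
             tsv = file.path(dir, "library.tsv"),
             tree = file.path(dir, "tree.nwk"),
             ranges = file.path(dir, "ranges.csv"))
  write_barcode_library(dataset$library, paths["fasta"], paths["tsv"])
  ape::write.tree(dataset$tree, paths["tree"])
  write.csv(dataset$ranges, paths["ranges"], row.names = FALSE)
  invisible(paths)
}
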