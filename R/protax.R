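#' Build the 4-level taxonomy tree of a reference library
#'
#' Root (order) -> families -> subfamilies -> genera -> species; each taxon
#' node holds the indices of the reference specimens it contains. The leaf
#' (species) reference sets partition the species-identified library.
#'
#' @param lib a `barcode_library` (genus-level records are dropped).
#' @return list with `taxa` (data.frame taxon/level/parent), `refs` (named
#'   list of specimen index vectors per taxon), `children` (named list per
#'   parent taxon), `species` (level-4 taxon names), `lib` (the
#'   species-identified library).
#' @export
build_taxonomy <- function(lib) {
  lib <- species_identified(lib)
  md <- lib$metadata
  lv <- list(md$family, md$subfamily, md$genus, md$species)
  parent_of <- list(rep("root", nrow(md)), md$family, md$subfamily, md$genus)
  taxa <- do.call(rbind, lapply(1:4, function(l) {
    u <- !duplicated(lv[[l]])
    data.frame(taxon = lv[[l]][u], level = l, parent = parent_of[[l]][u],
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(taxa$taxon))
    stop("taxon names must be unique across levels")
  refs <- lapply(1:4, function(l) split(seq_len(nrow(md)), lv[[l]]))
  refs <- do.call(c, refs)
  refs <- refs[taxa$taxon]
  children <- split(taxa$taxon, taxa$parent)
  structure(list(taxa = taxa, refs = refs, children = children,
                 species = taxa$taxon[taxa$level == 4L], lib = lib),
            class = "protax_taxonomy")
}

# d_min / d_avg from each query (rows of D) to each taxon's reference set.
# When loo = TRUE, D must be the symmetric reference-vs-reference matrix and
# each query is removed from every taxon containing it; a taxon emptied by
# the removal yields NA for that query.
taxon_predictors <- function(D, taxonomy, loo = FALSE) {
  nq <- nrow(D)
  out <- lapply(taxonomy$refs, function(ct) {
    cnt <- length(ct)
    sub <- D[, ct, drop = FALSE]
    avg <- rowSums(sub) / cnt
    mn <- do.call(pmin, c(as.data.frame(sub), na.rm = FALSE))
    if (loo) {
      for (i in ct) { # queries that are members of this taxon
        if (cnt == 1L) {
          avg[i] <- NA_real_; mn[i] <- NA_real_
        } else {
          rest <- setdiff(ct, i)
          avg[i] <- (avg[i] * cnt - D[i, i]) / (cnt - 1L)
          mn[i] <- min(D[i, rest])
        }
      }
    }
    cbind(d_min = mn, d_avg = avg)
  })
  names(out) <- taxonomy$taxa$taxon
  out
}

#' Multinomial node probabilities over candidate child taxa
#'
#' Softmax of a shared weight vector applied to each candidate's
#' standardized predictors: `p_k = exp(beta . x_k) / sum_j exp(beta . x_j)`
#' with `x_k = (1, z_min_k, z_avg_k)`. A single candidate receives
#' probability one regardless of `beta`.
#'
#' @param beta numeric length-3 weight vector (intercept, d_min, d_avg).
#' @param X K x 2 matrix of standardized (d_min, d_avg) predictors.
#' @return numeric simplex of length K.
#' @export
node_probabilities <- function(beta, X) {
  X <- rbind(X)
  stopifnot(length(beta) == 3L, ncol(X) == 2L)
  eta <- beta[1] + X %*% beta[2:3]
  eta <- eta - max(eta)
  as.numeric(exp(eta) / sum(exp(eta)))
}

#' Build the leave-one-out training set for the hierarchical classifier
#'
#' For every reference sequence, at each of the four levels along its true
#' taxonomic path, predictors (d_min, d_avg) to all candidate children of
#' the true parent are computed with the focal sequence removed from every
#' reference set; the label is the true child. Candidates emptied by the
#' removal are dropped; when the true child itself is emptied (singleton
#' species) the record's label is unreachable and is flagged.
#' Predictors are standardized to zero mean / unit variance per level; the
#' scaler is stored with the level.
#'
#' @param lib a `barcode_library`.
#' @param taxonomy optional [build_taxonomy()] result.
#' @param dm optional precomputed [p_distance_matrix()] of the
#'   species-identified library.
#' @param min_overlap passed to [p_distance_matrix()].
#' @return a `protax_training_set`: per level, padded predictor arrays
#'   (`Xmin`, `Xavg`, `mask`), label indices (`NA` = unreachable), the
#'   scaler, record bookkeeping; plus the taxonomy.
#' @export
build_training_set <- function(lib, taxonomy = NULL, dm = NULL,
                               min_overlap = 300L) {
  if (is.null(taxonomy)) taxonomy <- build_taxonomy(lib)
  slib <- taxonomy$lib
  if (is.null(dm)) dm <- p_distance_matrix(slib, min_overlap = min_overlap)
  D <- dm$p
  preds <- taxon_predictors(D, taxonomy, loo = TRUE)
  md <- slib$metadata
  path <- cbind(md$family, md$subfamily, md$genus, md$species)
  n <- nrow(md)
  levels <- vector("list", 4L)
  for (l in 1:4) {
    parents <- if (l == 1L) rep("root", n) else path[, l - 1L]
    cand_list <- taxonomy$children[parents]
    K_max <- max(lengths(cand_list))
    Xmin <- Xavg <- matrix(NA_real_, n, K_max)
    mask <- matrix(FALSE, n, K_max)
    label <- integer(n)
    cand_names <- vector("list", n)
    for (i in seq_len(n)) {
      cands <- cand_list[[i]]
      pm <- vapply(cands, function(tx) preds[[tx]][i, ], numeric(2))
      keep <- !is.na(pm[1, ])
      cands <- cands[keep]
      pm <- pm[, keep, drop = FALSE]
      k <- length(cands)
      if (k > 0L) {
        Xmin[i, seq_len(k)] <- pm[1, ]
        Xavg[i, seq_len(k)] <- pm[2, ]
        mask[i, seq_len(k)] <- TRUE
      }
      lbl <- match(path[i, l], cands)
      label[i] <- if (is.na(lbl)) NA_integer_ else lbl
      cand_names[[i]] <- cands
    }
    mu <- c(d_min = mean(Xmin[mask]), d_avg = mean(Xavg[mask]))
    sdv <- c(d_min = sd(Xmin[mask]), d_avg = sd(Xavg[mask]))
    sdv[sdv == 0 | is.na(sdv)] <- 1
    Z_min <- (Xmin - mu[1]) / sdv[1]
    Z_avg <- (Xavg - mu[2]) / sdv[2]
    Z_min[!mask] <- 0; Z_avg[!mask] <- 0
    levels[[l]] <- list(Xmin = Z_min, Xavg = Z_avg, mask = mask,
                        label = label, candidates = cand_names,
                        scaler = list(mean = mu, sd = sdv),
                        n_unreachable = sum(is.na(label)))
  }
  structure(list(levels = levels, taxonomy = taxonomy, dm = dm),
            class = "protax_training_set")
}

UNREACHABLE_FLOOR <- -30 # per-record log-likelihood floor when the true
                         # child has no remaining references

#' Log posterior of one level's weight vector
#'
#' Sum over training records of the log multinomial probability of the true
#' child plus independent zero-mean Gaussian log-priors (sd = 100) on the
#' weights. Records whose true child is unreachable contribute a constant
#' floor of -30 each (their count is reported by [build_training_set()]).
#'
#' @param beta length-3 weights (intercept, d_min, d_avg).
#' @param level one element of `protax_training_set$levels`.
#' @param prior_sd Gaussian prior standard deviation (default 100).
#' @return scalar log posterior.
#' @export
protax_log_posterior <- function(beta, level, prior_sd = 100) {
  eta <- beta[1] + beta[2] * level$Xmin + beta[3] * level$Xavg
  eta[!level$mask] <- -Inf
  m <- do.call(pmax, as.data.frame(eta))
  se <- rowSums(exp(eta - m) * level$mask)
  ok <- !is.na(level$label)
  idx <- cbind(which(ok), level$label[ok])
  loglik <- sum(eta[idx] - m[ok] - log(se[ok])) +
    UNREACHABLE_FLOOR * sum(!ok)
  loglik + sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
}

# Adaptive random-walk Metropolis for one level. Phase 1 adapts the
# proposal scale toward acceptance 0.44 (Robbins-Monro update on log-scale,
# diminishing gain t^-0.6); phase 2 runs with the proposal frozen. The MAP
# is the highest-posterior state visited during phase 2.
mcmc_level <- function(level, n_adapt = 1000L, n_iter = 1000L,
                       prior_sd = 100, init_scale = 0.1) {
  beta <- c(0, 0, 0)
  lp <- protax_log_posterior(beta, level, prior_sd)
  if (!is.finite(lp)) { beta <- c(0, 0, 0); lp <- protax_log_posterior(beta, level, prior_sd) }
  s <- init_scale
  total <- n_adapt + n_iter
  trace <- matrix(NA_real_, total, 3L)
  lp_trace <- numeric(total)
  accept <- logical(total)
  for (t in seq_len(total)) {
    prop <- beta + s * rnorm(3L)
    lp_prop <- protax_log_posterior(prop, level, prior_sd)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      beta <- prop; lp <- lp_prop; accept[t] <- TRUE
    }
    if (t <= n_adapt) s <- s * exp(t^-0.6 * (accept[t] - 0.44))
    trace[t, ] <- beta
    lp_trace[t] <- lp
  }
  phase2 <- seq(n_adapt + 1L, total)
  best <- phase2[which.max(lp_trace[phase2])]
  list(beta = trace[best, ], map_log_posterior = lp_trace[best],
       trace = trace, log_posterior = lp_trace, accept = accept,
       scale = s,
       acceptance_adapt = mean(accept[seq_len(n_adapt)]),
       acceptance_fixed = mean(accept[phase2]))
}

#' Train the hierarchical classifier by adaptive-proposal MCMC
#'
#' One weight vector (intercept, d_min, d_avg) per taxonomic level, shared
#' across all nodes of the level. Each level's chain runs `n_adapt`
#' iterations of random-walk Metropolis with the proposal scale adapted
#' toward an acceptance ratio of 0.44, then `n_iter` iterations with the
#' proposal fixed; the maximum-a-posteriori estimate is taken over the
#' fixed-proposal half.
#'
#' @param training a [build_training_set()] result (or a `barcode_library`,
#'   in which case the training set is built first).
#' @param n_adapt,n_iter iterations of the two phases (defaults 1000+1000).
#' @param seed RNG seed for the chains.
#' @param prior_sd Gaussian prior sd on the weights (default 100).
#' @return a `protax_model`: taxonomy, per-level `beta` (MAP), scaler,
#'   chain diagnostics, and the settings used.
#' @export
protax_train <- function(training, n_adapt = 1000L, n_iter = 1000L,
                         seed = 1L, prior_sd = 100) {
  if (inherits(training, "barcode_library"))
    training <- build_training_set(training)
  stopifnot(inherits(training, "protax_training_set"))
  set.seed(seed)
  chains <- lapply(training$levels, mcmc_level,
                   n_adapt = n_adapt, n_iter = n_iter, prior_sd = prior_sd)
  levels <- lapply(1:4, function(l) {
    list(beta = chains[[l]]$beta,
         scaler = training$levels[[l]]$scaler,
         map_log_posterior = chains[[l]]$map_log_posterior,
         acceptance_adapt = chains[[l]]$acceptance_adapt,
         acceptance_fixed = chains[[l]]$acceptance_fixed,
         scale = chains[[l]]$scale,
         n_unreachable = training$levels[[l]]$n_unreachable)
  })
  structure(list(taxonomy = training$taxonomy, levels = levels,
                 chains = chains,
                 settings = list(n_adapt = n_adapt, n_iter = n_iter,
                                 seed = seed, prior_sd = prior_sd)),
            class = "protax_model")
}

#' @export
print.protax_model <- function(x, ...) {
  cat("protax_model: 4 levels,", length(x$taxonomy$species), "species,",
      nrow(x$taxonomy$lib$metadata), "reference sequences\n")
  for (l in 1:4)
    cat(sprintf("  level %d beta = (%.3f, %.3f, %.3f) acc2 = %.2f\n", l,
                x$levels[[l]]$beta[1], x$levels[[l]]$beta[2],
                x$levels[[l]]$beta[3], x$levels[[l]]$acceptance_fixed))
  invisible(x)
}

# Shared classification engine: D is the n_query x n_ref p-distance matrix
# (symmetric reference matrix when loo = TRUE). Returns the per-species
# probability matrix and per-taxon path probabilities. Exhaustive over all
# branches (no pruning).
classify_engine <- function(model, D, loo = FALSE) {
  taxonomy <- model$taxonomy
  preds <- taxon_predictors(D, taxonomy, loo = loo)
  nq <- nrow(D)
  prob <- list(root = rep(1, nq))
  taxa <- taxonomy$taxa
  for (l in 1:4) {
    sc <- model$levels[[l]]$scaler
    beta <- model$levels[[l]]$beta
    parents <- unique(taxa$parent[taxa$level == l])
    for (pa in parents) {
      kids <- taxonomy$children[[pa]]
      kids <- kids[kids %in% taxa$taxon[taxa$level == l]]
      eta <- matrix(-Inf, nq, length(kids))
      for (k in seq_along(kids)) {
        pm <- preds[[kids[k]]]
        z_min <- (pm[, 1] - sc$mean[1]) / sc$sd[1]
        z_avg <- (pm[, 2] - sc$mean[2]) / sc$sd[2]
        e <- beta[1] + beta[2] * z_min + beta[3] * z_avg
        e[is.na(pm[, 1])] <- -Inf # candidate with no references
        eta[, k] <- e
      }
      m <- do.call(pmax, as.data.frame(eta))
      se <- rowSums(exp(eta - m))
      pk <- exp(eta - m) / se
      pk[!is.finite(m) | se == 0, ] <- 0 # all candidates excluded
      for (k in seq_along(kids))
        prob[[kids[k]]] <- prob[[pa]] * pk[, k]
    }
  }
  species <- taxonomy$species
  P <- do.call(cbind, prob[species])
  colnames(P) <- species
  rownames(P) <- rownames(D)
  list(species_prob = P, taxon_prob = prob)
}

#' Leave-one-out classification of every reference sequence
#'
#' Each species-identified barcode is classified down the 4-level taxonomy
#' with itself removed from all reference sets. The root carries
#' probability one; each node partitions its mass over candidate children
#' via [node_probabilities()]; a species' probability is the product of
#' branch probabilities along its path. Evaluation is exhaustive over all
#' branches.
#'
#' @param model a trained `protax_model`.
#' @param dm optional precomputed [p_distance_matrix()] of the model's
#'   reference library (reused from training when available).
#' @return list with `species_prob` (queries x species probability matrix),
#'   `true_species`, `correct_prob` (per specimen), `assignments`
#'   (data.frame: specimen_id, true_species, top_species, top_prob,
#'   correct_prob).
#' @export
protax_classify_loo <- function(model, dm = NULL) {
  slib <- model$taxonomy$lib
  if (is.null(dm)) dm <- p_distance_matrix(slib)
  eng <- classify_engine(model, dm$p, loo = TRUE)
  P <- eng$species_prob
  true_sp <- slib$metadata$species
  correct <- P[cbind(seq_len(nrow(P)), match(true_sp, colnames(P)))]
  # top species; ties broken lexicographically (columns are sorted by name
  # within genus construction order, so order by name first)
  ord <- order(colnames(P))
  Po <- P[, ord, drop = FALSE]
  top_idx <- max.col(Po, ties.method = "first")
  assignments <- data.frame(
    specimen_id = slib$metadata$specimen_id,
    true_species = true_sp,
    top_species = colnames(Po)[top_idx],
    top_prob = Po[cbind(seq_len(nrow(Po)), top_idx)],
    correct_prob = correct,
    stringsAsFactors = FALSE)
  list(species_prob = P, taxon_prob = eng$taxon_prob,
       true_species = true_sp, correct_prob = correct,
       assignments = assignments)
}

#' Classify query sequences against a trained model
#'
#' @param model a trained `protax_model`.
#' @param queries named character vector of aligned query sequences (same
#'   frame as the reference library).
#' @param exclude_id optional specimen id removed from all reference sets
#'   (manual leave-one-out for a single query).
#' @param min_overlap minimum compared sites for a valid query-reference
#'   pair.
#' @return list with `species_prob` (queries x species), `taxon_prob`, and
#'   `assignments` (top species per query).
#' @export
protax_classify <- function(model, queries, exclude_id = NULL,
                            min_overlap = 300L) {
  slib <- model$taxonomy$lib
  ref_m <- sequence_matrix(slib)
  q_chars <- strsplit(toupper(queries), "", fixed = TRUE)
  stopifnot(all(lengths(q_chars) == slib$L))
  qm <- matrix(match(unlist(q_chars), DNA_BASES),
               nrow = length(queries), ncol = slib$L, byrow = TRUE)
  rownames(qm) <- names(queries)
  vq <- !is.na(qm); vr <- !is.na(ref_m)
  storage.mode(vq) <- storage.mode(vr) <- "double"
  compared <- vq %*% t(vr)
  matches <- matrix(0, nrow(qm), nrow(ref_m))
  for (b in 1:4) {
    iq <- vq * (qm == b); iq[is.na(iq)] <- 0
    ir <- vr * (ref_m == b); ir[is.na(ir)] <- 0
    matches <- matches + iq %*% t(ir)
  }
  D <- (compared - matches) / compared
  D[compared < min_overlap] <- NA_real_
  if (!is.null(exclude_id)) {
    keep <- slib$metadata$specimen_id != exclude_id
    # removing a reference changes taxon sets; emulate by setting its
    # distances to NA-safe large values is wrong for d_avg, so rebuild
    sub <- subset_library(slib, keep)
    model2 <- model
    model2$taxonomy <- build_taxonomy(sub)
    return(protax_classify(model2, queries, min_overlap = min_overlap))
  }
  if (anyNA(D)) {
    unassignable <- rowSums(!is.na(D)) == 0
    if (any(unassignable))
      warning(sum(unassignable), " query(ies) share no valid overlap with ",
              "any reference and are unassignable")
    D[is.na(D)] <- 1 # worst-case distance for sparse invalid pairs
  }
  eng <- classify_engine(model, D, loo = FALSE)
  P <- eng$species_prob
  ord <- order(colnames(P))
  Po <- P[, ord, drop = FALSE]
  top_idx <- max.col(Po, ties.method = "first")
  list(species_prob = P, taxon_prob = eng$taxon_prob,
       assignments = data.frame(
         query = rownames(P) %||% seq_len(nrow(P)),
         top_species = colnames(Po)[top_idx],
         top_prob = Po[cbind(seq_len(nrow(Po)), top_idx)],
         stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-species mean probability of correct identification
#'
#' Averages the probability assigned to the true species over each species'
#' specimens, and reports the specimen-weighted cohort mean alongside
#' (the two differ whenever sampling is uneven).
#'
#' @param loo result of [protax_classify_loo()].
#' @param drop_singletons exclude species represented by a single specimen
#'   (their leave-one-out correct probability is identically zero).
#' @return list with `per_species` (data.frame species/n/mean_correct),
#'   `specimen_weighted_mean`, `species_mean`.
#' @export
species_average_probability <- function(loo, drop_singletons = TRUE) {
  df <- data.frame(species = loo$true_species, p = loo$correct_prob,
                   stringsAsFactors = FALSE)
  agg <- aggregate(p ~ species, df, mean)
  cnt <- aggregate(p ~ species, df, length)
  per <- data.frame(species = agg$species, n = cnt$p,
                    mean_correct = agg$p, stringsAsFactors = FALSE)
  if (drop_singletons) {
    kept <- per$n > 1L
    sw <- mean(df$p[df$species %in% per$species[kept]])
    per_out <- per[kept, , drop = FALSE]
  } else {
    sw <- mean(df$p)
    per_out <- per
  }
  rownames(per_out) <- NULL
  list(per_species = per_out,
       specimen_weighted_mean = sw,
       species_mean = mean(per_out$mean_correct))
}

#' Serialize a trained model to versioned JSON
#'
#' Stores the taxonomy (taxa table and per-taxon specimen ids), per-level
#' weights and scalers, chain summaries and training settings. The
#' reference library itself is not embedded; [read_protax_model()] takes it
#' as an argument.
#' @param model a `protax_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_protax_model <- function(model, path) {
  slib <- model$taxonomy$lib
  obj <- list(
    format = "barcodelib-protax", version = 1L,
    settings = model$settings,
    taxa = model$taxonomy$taxa,
    refs = lapply(model$taxonomy$refs, function(i)
      slib$metadata$specimen_id[i]),
    levels = lapply(model$levels, function(lv)
      list(beta = lv$beta,
           scaler_mean = as.numeric(lv$scaler$mean),
           scaler_sd = as.numeric(lv$scaler$sd),
           map_log_posterior = lv$map_log_posterior,
           acceptance_adapt = lv$acceptance_adapt,
           acceptance_fixed = lv$acceptance_fixed,
           n_unreachable = lv$n_unreachable)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model back, reattaching its reference library
#' @param path JSON file written by [write_protax_model()].
#' @param lib the `barcode_library` the model was trained on.
#' @return a `protax_model` (without full chain traces).
#' @export
read_protax_model <- function(path, lib) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "barcodelib-protax"))
    stop("not a barcodelib protax model file")
  taxonomy <- build_taxonomy(lib)
  levels <- lapply(obj$levels, function(lv)
    list(beta = as.numeric(unlist(lv$beta)),
         scaler = list(mean = as.numeric(unlist(lv$scaler_mean)),
                       sd = as.numeric(unlist(lv$scaler_sd))),
         map_log_posterior = lv$map_log_posterior,
         acceptance_adapt = lv$acceptance_adapt,
         acceptance_fixed = lv$acceptance_fixed,
         n_unreachable = lv$n_unreachable))
  structure(list(taxonomy = taxonomy, levels = levels, chains = NULL,
                 settings = obj$settings),
            class = "protax_model")
}
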