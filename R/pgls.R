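#' Brownian-motion phylogenetic covariance of a tree
#'
#' Shared root-to-tip path lengths (`ape::vcv`), optionally restricted and
#' reordered to a species set.
#' @param tree an `ape::phylo` with branch lengths.
#' @param species optional species names (must all be tips).
#' @return symmetric covariance matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL) {
  V <- ape::vcv(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(V))
    if (length(missing))
      stop("species absent from tree: ", paste(head(missing, 5),
                                               collapse = ", "))
    V <- V[species, species]
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda` while leaving the
#' diagonal unchanged: `lambda = 1` returns the Brownian expectation,
#' `lambda = 0` a star phylogeny (independent tips).
#' @param V covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# ML Gaussian GLS at a fixed lambda: coefficients, RSS on the whitened
# scale and the profile log-likelihood.
gls_at_lambda <- function(y, X, V, lambda) {
  n <- length(y)
  Vl <- lambda_transform(V, lambda)
  ch <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  # whiten: solve L' z = x with V = L'L (chol gives upper U, V = U'U)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(Xw)) stop("singular design under V^-1 weighting")
  beta <- qr.coef(qr_x, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + 2 * sum(log(diag(ch))) + n)
  list(beta = beta, rss = rss, logL = logL, chol = ch, Xw = Xw, yw = yw)
}

#' Phylogenetic generalised least squares with Pagel's lambda
#'
#' Fits `y ~ X` by maximum likelihood with residual covariance
#' `sigma^2 * V_lambda`, profiling the likelihood over lambda on a
#' 101-point grid followed by golden-section refinement. Standard errors
#' use `RSS/(n-k)` and two-sided t p-values carry `n-k` degrees of
#' freedom. R-squared is reported on the lambda-whitened scale (and, for
#' reference, on the raw scale). AICc counts the coefficients plus sigma^2
#' and lambda as parameters.
#'
#' @param y numeric response (named by species, or aligned with `V`).
#' @param X predictor matrix or data.frame (an intercept column is added).
#' @param V phylogenetic covariance from [phylo_covariance()].
#' @param lambda fix lambda instead of profiling (optional).
#' @return a `pgls_fit`: coefficients table (Estimate, SE, t, P), `lambda`,
#'   `logL`, `n`, `k`, `r_squared` (whitened), `r_squared_raw`, `aicc`,
#'   `sigma2`.
#' @export
pgls_fit <- function(y, X, V, lambda = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  if (!is.null(rownames(V)) && !is.null(names(y))) {
    stopifnot(setequal(names(y), rownames(V)))
    X <- X[match(rownames(V), names(y)), , drop = FALSE]
    y <- y[rownames(V)]
  }
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  prof <- function(lm_) {
    f <- gls_at_lambda(y, Xd, V, lm_)
    if (is.null(f)) -Inf else f$logL
  }
  if (is.null(lambda)) {
    grid <- seq(0, 1, length.out = 101)
    ll <- vapply(grid, prof, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    gr <- (sqrt(5) - 1) / 2 # golden-section refinement
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    fc <- prof(c1); fd <- prof(d1)
    while (b - a > 1e-6) {
      if (fc > fd) { b <- d1; d1 <- c1; fd <- fc
                     c1 <- b - gr * (b - a); fc <- prof(c1) }
      else { a <- c1; c1 <- d1; fc <- fd
             d1 <- a + gr * (b - a); fd <- prof(d1) }
    }
    lambda <- (a + b) / 2
    if (prof(grid[i]) > prof(lambda)) lambda <- grid[i]
  }
  fit <- gls_at_lambda(y, Xd, V, lambda)
  if (is.null(fit)) stop("V_lambda is not positive definite")
  k <- ncol(Xd)
  sigma2 <- fit$rss / (n - k)
  XtX_inv <- chol2inv(qr.R(qr(fit$Xw)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- as.numeric(fit$beta) / se
  pval <- 2 * pt(-abs(tval), df = n - k)
  coefs <- data.frame(Estimate = as.numeric(fit$beta), SE = se,
                      t = tval, P = pval,
                      row.names = colnames(Xd))
  # whitened R^2 against the GLS intercept-only model
  null_fit <- gls_at_lambda(y, matrix(1, n, 1), V, lambda)
  r2_white <- 1 - fit$rss / null_fit$rss
  yhat <- as.numeric(Xd %*% fit$beta)
  r2_raw <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  k_aicc <- k + 2 # + sigma^2 and lambda
  aicc_val <- if (n > k_aicc + 1) aicc(fit$logL, k_aicc, n) else NA_real_
  structure(list(coefficients = coefs, lambda = lambda, logL = fit$logL,
                 n = n, k = k, sigma2 = sigma2,
                 r_squared = r2_white, r_squared_raw = r2_raw,
                 aicc = aicc_val,
                 fitted = yhat, residuals = y - yhat),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: n = %d, lambda = %.3f, logL = %.3f, AICc = %.2f\n",
              x$n, x$lambda, x$logL, x$aicc))
  cat(sprintf("R^2 (whitened) = %.3f, R^2 (raw) = %.3f\n",
              x$r_squared, x$r_squared_raw))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2 \log L + 2k + \frac{2k(k+1)}{n-k-1}}
#' @param logL log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (`n > k + 1`).
#' @return scalar.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare PGLS fits by AICc
#'
#' Delta-AICc against the best model; models with a difference above 2 are
#' flagged distinguishable from the best (strictly greater).
#' @param fits named list of `pgls_fit` objects sharing response and n.
#' @return data.frame: model, aicc, delta_aicc, distinguishable.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits have different n; not comparable")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- a - min(a)
  out <- data.frame(model = names(fits) %||% seq_along(fits),
                    aicc = a, delta_aicc = delta,
                    distinguishable = delta > 2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$aicc), ]
}
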