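#' LASSO / stability-selection configuration
#'
#' @param n_lambda length of the penalty grid (log-spaced from the data's
#'   `lambda_max` down to `lambda_min_ratio * lambda_max`).
#' @param lambda_min_ratio ratio defining the small end of the grid.
#' @param n_folds cross-validation folds for per-sample penalty tuning.
#' @param n_bootstrap number of bootstrap resamples.
#' @param inclusion_threshold relevance rule: variables with inclusion
#'   frequency strictly greater than this are relevant.
#' @param zero_tol coefficients with absolute value above this count as
#'   included (coordinate descent produces exact zeros; the tolerance is a
#'   guard).
#' @param tol coordinate-descent convergence tolerance (max coefficient
#'   change per sweep).
#' @param max_sweeps sweep budget; a fit stops at the tolerance or at this
#'   budget, whichever comes first.
#' @param seed base seed; bootstrap `b` uses stream `seed + b`.
#' @return list of class `"lasso_config"`.
#' @export
lasso_config <- function(n_lambda = 100, lambda_min_ratio = 1e-3,
                         n_folds = 10, n_bootstrap = 1000,
                         inclusion_threshold = 0.20, zero_tol = 1e-12,
                         tol = 1e-8, max_sweeps = 1e5, seed = 1L) {
  stopifnot(n_folds >= 2, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1, inclusion_threshold > 0,
            inclusion_threshold < 1)
  structure(list(n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_folds = n_folds, n_bootstrap = n_bootstrap,
                 inclusion_threshold = inclusion_threshold,
                 zero_tol = zero_tol, tol = tol,
                 max_sweeps = as.integer(max_sweeps), seed = as.integer(seed)),
            class = "lasso_config")
}

lambda_grid <- function(lmax, config) {
  if (lmax <= 0) return(rep(0, config$n_lambda))
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Fit the LASSO at one or more penalty values
#'
#' Minimizes `(1/2n)||y - b0 - X b||^2 + lambda ||b||_1` by cyclic
#' coordinate descent with soft-thresholding; the intercept is
#' unpenalized (`b0 = mean(y)` on the standardized, centered problem).
#' A decreasing `lambda` vector is fitted as a warm-started path.
#'
#' @param design an `iron_design` (or list with standardized `X` and `y`).
#' @param lambda penalty value(s), non-negative, decreasing if several.
#' @param config a [lasso_config()] (for `tol`/`max_sweeps`).
#' @return matrix of coefficients (p x length(lambda)) on the standardized
#'   scale, with the intercept as attribute `"intercept"` and rownames =
#'   design columns. Iteration stops per penalty when the maximum
#'   coefficient change falls below `tol` or the sweep budget is reached;
#'   attribute `"converged"` records which penalties met the tolerance.
#'   Non-finite coefficients (divergence) raise an error.
#' @export
fit_lasso <- function(design, lambda, config = lasso_config()) {
  stopifnot(all(lambda >= 0))
  if (length(lambda) > 1 && any(diff(lambda) > 0))
    stop("lambda path must be decreasing")
  X <- design$X; y <- design$y
  yc <- y - mean(y)
  beta <- cd_lasso_path(X, yc, lambda, config$tol, config$max_sweeps)
  if (!all(is.finite(beta)))
    stop("coordinate descent diverged (non-finite coefficients) at lambda = ",
         paste(format(lambda[colSums(!is.finite(beta)) > 0]), collapse = ", "))
  rownames(beta) <- colnames(X)
  attr(beta, "intercept") <- mean(y)
  beta
}

# out-of-fold prediction error over the lambda grid, with the training
# folds re-standardized; predictions are made on the raw (unstandardized)
# scale by back-transforming the coefficients
cv_error <- function(X_raw, y, grid, folds, config) {
  k <- max(folds)
  err <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sum(!tr) < 1 || sum(tr) < 2) stop("fold with too few observations")
    st <- standardize_matrix(X_raw[tr, , drop = FALSE])
    ytr <- y[tr]
    des <- list(X = st$X, y = ytr)
    beta <- fit_lasso(des, grid, config)
    b_orig <- beta / st$scale
    icpt <- mean(ytr) - as.numeric(crossprod(st$center, b_orig))
    pred <- X_raw[!tr, st$keep, drop = FALSE] %*% b_orig +
      matrix(icpt, sum(!tr), length(grid), byrow = TRUE)
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  colMeans(err)
}

#' Cross-validated penalty selection
#'
#' Assigns observations to `n_folds` folds by a seeded random permutation
#' and picks the penalty minimizing the mean out-of-fold squared error
#' over the grid (CV-minimum rule; ties broken toward the larger, more
#' parsimonious penalty).
#'
#' @param design an `iron_design` (or list with `X_raw` or `X`, and `y`).
#' @param config a [lasso_config()].
#' @param grid optional penalty grid; defaults to the design's
#'   `lambda_max`-anchored log grid.
#' @return list with `lambda` (the selected value), `grid` and `cv_mse`.
#' @export
cv_select_lambda <- function(design, config = lasso_config(), grid = NULL) {
  X_raw <- if (!is.null(design$X_raw)) design$X_raw else design$X
  y <- design$y
  n <- nrow(X_raw)
  if (n < config$n_folds) stop("need at least n_folds observations")
  if (is.null(grid)) {
    st <- standardize_matrix(X_raw)
    grid <- lambda_grid(lambda_max(st$X, y), config)
  }
  folds <- sample(rep_len(seq_len(config$n_folds), n))
  mse <- cv_error(X_raw, y, grid, folds, config)
  best <- which(mse <= min(mse) + 0)[1L]  # grid is decreasing: first = largest
  list(lambda = grid[best], grid = grid, cv_mse = mse)
}
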