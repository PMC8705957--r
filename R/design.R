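#' Build a regression design matrix from a cohort
#'
#' Turns the candidate variable panel into a numeric n x p design:
#' categorical variables are dummy-coded against their reference level
#' (each dummy is a separate column, penalized individually), variables
#' flagged in the catalog are natural-log transformed (zeros shifted by
#' half the smallest positive value), and every column is standardized to
#' mean 0, SD 1. The outcome is kept on its original scale (s^-1 for
#' hepatic iron); only centering is applied at fit time.
#'
#' Requires complete cases: run [apply_exclusions()] first.
#'
#' @param cohort an `iron_cohort` (one sex stratum, typically).
#' @param panel a [variable_panel()]; defaults to the catalog's candidates.
#' @param outcome outcome variable name (default `"hic"`).
#' @return object of class `"iron_design"`: list with standardized matrix
#'   `X`, unstandardized transformed matrix `X_raw`, outcome `y`, per-column
#'   `center`/`scale`, `column_names` and `source_var` (design column ->
#'   originating variable).
#' @export
build_design <- function(cohort, panel = default_panel(cohort$panel),
                         outcome = "hic") {
  d <- cohort$data
  vars <- intersect(c(panel$forced_names, panel$candidate_names), names(d))
  absent <- setdiff(c(panel$forced_names, panel$candidate_names), names(d))
  if (length(absent))
    warning("panel variables absent from cohort, skipped: ",
            paste(absent, collapse = ", "))
  if (!(outcome %in% names(d))) stop("outcome column not found: ", outcome)
  used <- d[, c(outcome, vars), drop = FALSE]
  if (any(!complete.cases(used)))
    stop("design requires complete cases; apply_exclusions() first")
  cols <- list()
  src <- character()
  for (v in vars) {
    sp <- cohort$panel[[v]]
    x <- d[[v]]
    if (!is.null(sp) && sp$dtype == "categorical") {
      lev <- setdiff(sp$levels, sp$ref)
      for (l in lev) {
        cols[[paste0(v, "_", l)]] <- as.numeric(x == l)
        src <- c(src, v)
      }
    } else {
      x <- as.numeric(x)
      nm <- v
      if (!is.null(sp) && isTRUE(sp$log)) {
        if (any(x < 0)) stop("negative values in log-flagged variable ", v)
        if (any(x == 0)) {
          shift <- min(x[x > 0]) / 2
          x <- x + shift
        }
        x <- log(x)
        nm <- paste0("log_", v)
      }
      cols[[nm]] <- x
      src <- c(src, v)
    }
  }
  X_raw <- do.call(cbind, cols)
  colnames(X_raw) <- names(cols)
  sds <- apply(X_raw, 2, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance design column(s): ",
         paste(colnames(X_raw)[zero], collapse = ", "))
  ctr <- colMeans(X_raw)
  X <- scale(X_raw, center = ctr, scale = sds)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(list(X = X, X_raw = X_raw, y = as.numeric(d[[outcome]]),
                 column_names = colnames(X_raw), source_var = src,
                 center = ctr, scale = sds, outcome = outcome,
                 n = nrow(X_raw), p = ncol(X_raw)),
            class = "iron_design")
}

#' @export
print.iron_design <- function(x, ...) {
  cat("Design matrix:", x$n, "observations x", x$p, "columns, outcome",
      x$outcome, "\n")
  invisible(x)
}

# standardize an unscaled matrix, dropping zero-variance columns
standardize_matrix <- function(X_raw) {
  n <- nrow(X_raw)
  m <- colMeans(X_raw)
  sds <- sqrt(pmax(colSums(X_raw^2) - n * m^2, 0) / (n - 1))
  keep <- sds > 1e-12 & is.finite(sds)
  Xc <- sweep(X_raw[, keep, drop = FALSE], 2, m[keep], "-")
  Xs <- sweep(Xc, 2, sds[keep], "/")
  list(X = Xs, center = m[keep], scale = sds[keep], keep = keep)
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the objective `(1/2n)||y - b0 - X b||^2 + lambda ||b||_1` on a
#' standardized design, `lambda_max = max_j |x_j' (y - mean(y))| / n`;
#' fitting at any `lambda >= lambda_max` yields the all-zero coefficient
#' vector.
#'
#' @param design an `iron_design`, or a bare standardized matrix with
#'   `y` supplied.
#' @param y outcome (only when `design` is a matrix).
#' @return scalar penalty.
#' @export
lambda_max <- function(design, y = NULL) {
  if (inherits(design, "iron_design")) {
    X <- design$X; y <- design$y
  } else X <- design
  yc <- y - mean(y)
  max(abs(crossprod(X, yc))) / nrow(X)
}
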