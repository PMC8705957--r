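#' Bootstrap stability selection for factors associated with hepatic iron
#'
#' The package's core fitting function. For each of `n_bootstrap`
#' resamples (rows drawn with replacement, seeded as `seed + b`): the
#' design is re-standardized within the resample, the penalty is tuned by
#' 10-fold cross-validation on that resample, the LASSO is fitted at the
#' selected penalty, and every design column with a nonzero coefficient is
#' marked as included. The per-column inclusion frequency across resamples
#' quantifies relative importance; columns with frequency strictly above
#' the threshold (default 20%) are flagged relevant.
#'
#' Columns that become constant inside a resample are dropped for that
#' resample and count as not included (logged in the result).
#'
#' @param design an `iron_design` from [build_design()], or an
#'   `iron_cohort` (in which case `panel`/`outcome` are used to build one).
#' @param config a [lasso_config()].
#' @param panel,outcome passed to [build_design()] when `design` is a
#'   cohort.
#' @return object of class `"stabsel"`: data frame accessor via
#'   `summary()`, with elements `inclusion` (data frame of variable,
#'   inclusion_frequency, relevant), `lambdas` (per-bootstrap selected
#'   penalty), `B`, `threshold`, `dropped` (per-column count of
#'   zero-variance drops), `config`, `call`.
#' @seealso [select_relevant()], [plot.stabsel()]
#' @export
stability_select <- function(design, config = lasso_config(),
                             panel = NULL, outcome = "hic") {
  cl <- match.call()
  if (inherits(design, "iron_cohort")) {
    if (is.null(panel)) panel <- default_panel(design$panel)
    design <- build_design(design, panel, outcome)
  }
  X_raw <- design$X_raw
  y <- design$y
  n <- nrow(X_raw); p <- ncol(X_raw)
  B <- config$n_bootstrap
  counts <- setNames(numeric(p), colnames(X_raw))
  dropped <- setNames(numeric(p), colnames(X_raw))
  lambdas <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(config$seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    Xb_raw <- X_raw[idx, , drop = FALSE]
    yb <- y[idx]
    st <- standardize_matrix(Xb_raw)
    if (any(!st$keep)) dropped[!st$keep] <- dropped[!st$keep] + 1
    grid <- lambda_grid(lambda_max(st$X, yb), config)
    sel <- cv_select_lambda(list(X_raw = Xb_raw[, st$keep, drop = FALSE],
                                 y = yb),
                            config, grid = grid)
    beta <- fit_lasso(list(X = st$X, y = yb), sel$lambda, config)
    inc <- abs(beta[, 1L]) > config$zero_tol
    counts[names(inc)[inc]] <- counts[names(inc)[inc]] + 1
    lambdas[b] <- sel$lambda
  }
  freq <- counts / B
  inclusion <- data.frame(
    variable = names(freq),
    inclusion_frequency = unname(freq),
    relevant = unname(freq > config$inclusion_threshold),
    row.names = NULL
  )
  inclusion <- inclusion[order(-inclusion$inclusion_frequency,
                               inclusion$variable), ]
  rownames(inclusion) <- NULL
  structure(list(inclusion = inclusion, lambdas = lambdas, B = B,
                 threshold = config$inclusion_threshold, dropped = dropped,
                 n = n, p = p, config = config, call = cl),
            class = "stabsel")
}

#' Relevant variables from a stability-selection fit
#'
#' Applies the strict `> threshold` rule and returns the variable names
#' ordered by descending inclusion frequency.
#'
#' @param result a `stabsel` object.
#' @param threshold inclusion-frequency threshold (default: the one the
#'   fit was run with).
#' @return character vector of relevant design columns.
#' @export
select_relevant <- function(result, threshold = result$threshold) {
  inc <- result$inclusion
  inc <- inc[inc$inclusion_frequency > threshold, ]
  inc$variable[order(-inc$inclusion_frequency, inc$variable)]
}

#' @export
print.stabsel <- function(x, ...) {
  cat("Bootstrap stability selection:", x$B, "resamples,", x$p,
      "candidate columns, n =", x$n, "\n")
  rel <- select_relevant(x)
  cat("Relevant (inclusion frequency >", x$threshold, "):",
      if (length(rel)) paste(rel, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
summary.stabsel <- function(object, ...) {
  out <- object$inclusion
  attr(out, "B") <- object$B
  attr(out, "threshold") <- object$threshold
  out
}

#' @export
coef.stabsel <- function(object, ...) {
  setNames(object$inclusion$inclusion_frequency, object$inclusion$variable)
}

#' Bar plot of inclusion frequencies
#'
#' Horizontal bar diagram of per-variable bootstrap inclusion
#' frequencies, descending, with the relevance threshold drawn as a
#' vertical line. By default only relevant variables are shown (as in the
#' published bar diagrams).
#'
#' @param x a `stabsel` object.
#' @param all show all columns, not only the relevant ones.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.stabsel <- function(x, all = FALSE, ...) {
  inc <- x$inclusion
  if (!all) inc <- inc[inc$relevant, , drop = FALSE]
  if (nrow(inc) == 0) {
    warning("no relevant variables to plot")
    return(invisible(x))
  }
  inc <- inc[order(inc$inclusion_frequency), ]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(inc$inclusion_frequency, names.arg = inc$variable,
                    horiz = TRUE, las = 1,
                    xlab = "bootstrap inclusion frequency", xlim = c(0, 1),
                    ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
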