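#' Unpenalized adjusted regression for one exposure
#'
#' Ordinary least squares of hepatic iron content on one exposure,
#' adjusted for age alone or for age plus log hepatic fat fraction.
#' Exposures flagged in the catalog are natural-log transformed first
#' (zeros shifted by half the smallest positive value, as in the design
#' stage). Reports the unstandardized coefficient (s^-1 per exposure
#' unit), its 95% t-interval, the two-sided p-value and the full-model
#' adjusted R^2.
#'
#' @param cohort an `iron_cohort` (one sex stratum; complete cases on the
#'   involved columns are used).
#' @param exposure exposure variable name (for categoricals, a design-style
#'   dummy name such as `"diabetes_status_prediabetes"` is also accepted).
#' @param adjust character vector of adjusters: `"age"` or
#'   `c("age", "hff")` (HFF enters log-transformed).
#' @param outcome outcome column (default `"hic"`).
#' @return list of class `"iron_regression"` with `exposure`, `adjustment`,
#'   `beta`, `ci_low`, `ci_high`, `p`, `adj_r2`, `n`.
#' @export
fit_adjusted_model <- function(cohort, exposure, adjust = c("age", "hff"),
                               outcome = "hic") {
  d <- cohort$data
  if (exposure %in% adjust)
    stop("exposure coincides with an adjustment variable: ", exposure)
  get_col <- function(v) {
    if (v %in% names(d)) {
      sp <- cohort$panel[[v]]
      x <- d[[v]]
      if (!is.null(sp) && sp$dtype == "categorical")
        stop("categorical exposure must be given as a dummy name, e.g. ",
             v, "_", setdiff(sp$levels, sp$ref)[1L])
      x <- as.numeric(x)
      if (!is.null(sp) && isTRUE(sp$log)) {
        if (any(x == 0, na.rm = TRUE))
          x <- x + min(x[x > 0], na.rm = TRUE) / 2
        x <- log(x)
      }
      return(x)
    }
    # dummy-coded categorical level, e.g. diabetes_status_prediabetes
    for (v0 in names(cohort$panel)) {
      sp <- cohort$panel[[v0]]
      if (sp$dtype == "categorical" && startsWith(v, paste0(v0, "_"))) {
        lev <- substring(v, nchar(v0) + 2)
        if (lev %in% sp$levels) return(as.numeric(d[[v0]] == lev))
      }
    }
    stop("variable not found in cohort: ", v)
  }
  y <- as.numeric(d[[outcome]])
  xs <- list(exposure = get_col(exposure))
  for (a in adjust) xs[[a]] <- get_col(a)
  mf <- data.frame(y = y, xs)
  mf <- mf[complete.cases(mf), , drop = FALSE]
  if (nrow(mf) <= length(xs) + 1) stop("too few complete cases")
  fit <- lm(y ~ ., data = mf)
  sm <- summary(fit)
  ci <- confint(fit, "exposure", level = 0.95)
  structure(list(exposure = exposure,
                 adjustment = paste(adjust, collapse = "+"),
                 beta = unname(coef(fit)["exposure"]),
                 ci_low = ci[1L], ci_high = ci[2L],
                 p = sm$coefficients["exposure", 4L],
                 adj_r2 = sm$adj.r.squared,
                 n = nrow(mf)),
            class = "iron_regression")
}

#' @export
print.iron_regression <- function(x, ...) {
  cat(sprintf("%s (%s-adjusted): beta = %.3f [%.3f; %.3f], p = %s, adj R2 = %.3f (n = %d)\n",
              x$exposure, x$adjustment, x$beta, x$ci_low, x$ci_high,
              format.pval(x$p, digits = 2), x$adj_r2, x$n))
  invisible(x)
}

#' Effect table for the selected variables
#'
#' For each selected variable fits both adjustment sets (age-only and
#' age + log-HFF); the hepatic fat fraction itself gets the age-only model
#' only. Variables absent from the cohort are skipped with a warning.
#' This reproduces the published effect-table schema: variable,
#' adjustment, beta, 95% CI, p, adjusted R^2.
#'
#' @param cohort an `iron_cohort` stratum.
#' @param selected character vector of selected design columns (names as
#'   produced by [build_design()], e.g. `"log_hff"`,
#'   `"diabetes_status_prediabetes"`).
#' @return data frame, one row per (variable, adjustment).
#' @export
run_effect_table <- function(cohort, selected) {
  if (length(selected) == 0) stop("selected set must be non-empty")
  rows <- list()
  for (v in selected) {
    v0 <- sub("^log_", "", v)
    if (!(v0 %in% names(cohort$data)) &&
        !any(vapply(names(cohort$panel), function(p0)
          startsWith(v0, paste0(p0, "_")), TRUE))) {
      warning("selected variable absent from cohort, skipped: ", v0)
      next
    }
    adjsets <- if (v0 == "hff") list("age")
    else if (v0 == "age") list("hff")
    else list(c("age", "hff"), "age")
    for (a in adjsets) {
      r <- fit_adjusted_model(cohort, v0, a)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, adjustment = r$adjustment, beta = r$beta,
        ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
        adj_r2 = r$adj_r2, n = r$n, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
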