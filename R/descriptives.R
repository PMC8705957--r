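#' Summarize one variable
#'
#' Descriptive summary in either `mean_sd` or `median_iqr` style
#' (quartiles by linear interpolation, quantile type 7). Missing values
#' are excluded and the non-missing `n` is reported.
#'
#' @param values numeric vector.
#' @param style `"mean_sd"` or `"median_iqr"`.
#' @return list with `n`, `mean`, `sd`, `median`, `iqr`, `style`.
#' @export
summarize_variable <- function(values, style = c("mean_sd", "median_iqr")) {
  style <- match.arg(style)
  x <- values[!is.na(values)]
  if (length(x) == 0) stop("all values missing")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), mean = mean(x), sd = sd(x),
       median = q[2], iqr = q[3] - q[1], style = style)
}

#' Summarize a categorical variable
#'
#' @param values character or factor vector.
#' @return data frame with level, count and percent (of non-missing).
#' @export
summarize_categorical <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) == 0) stop("all values missing")
  tab <- table(x)
  data.frame(level = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(x),
             row.names = NULL)
}

new_test_result <- function(statistic, df, p, method, estimate = NA_real_) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), method = method,
                 estimate = unname(estimate)),
            class = "iron_test")
}

#' @export
print.iron_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", format(x$df, digits = 4)),
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Two-group comparison
#'
#' Compares a variable between two groups with the test a descriptive
#' table would use: Welch's t-test for symmetric continuous variables,
#' Mann-Whitney U for skewed ones, chi-square (without continuity
#' correction) for categoricals. `method = "auto"` routes by type and a
#' |skewness| > 1 rule on the pooled values. P-values are two-sided and
#' never adjusted for multiplicity.
#'
#' @param x,y values in the two groups (numeric, or character/factor for
#'   chi-square).
#' @param method `"auto"`, `"welch_t"`, `"mann_whitney"` or `"chi_square"`.
#' @return an `iron_test` result.
#' @export
compare_two_groups <- function(x, y,
                               method = c("auto", "welch_t", "mann_whitney",
                                          "chi_square")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  categorical <- !is.numeric(x) || !is.numeric(y)
  if (method == "auto") {
    method <- if (categorical) "chi_square"
    else if (abs(sample_skewness(c(x, y))) > 1) "mann_whitney"
    else "welch_t"
  }
  if (method == "chi_square") {
    lev <- sort(unique(c(as.character(x), as.character(y))))
    if (length(lev) < 2) stop("chi-square requires at least 2 levels")
    tab <- rbind(table(factor(x, lev)), table(factor(y, lev)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(new_test_result(ct$statistic, ct$parameter, ct$p.value,
                           "chi_square"))
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    warning("degenerate comparison: zero variance in both groups")
    return(new_test_result(0, NA_real_, 1, method))
  }
  if (method == "welch_t") {
    tt <- t.test(x, y, var.equal = FALSE)
    new_test_result(tt$statistic, tt$parameter, tt$p.value, "welch_t",
                    tt$estimate[[1]] - tt$estimate[[2]])
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    new_test_result(wt$statistic, NA_real_, wt$p.value, "mann_whitney")
  }
}

#' Welch's t-test from printed summary statistics
#'
#' Computes the Welch statistic, Satterthwaite degrees of freedom, and the
#' two-sided p-value from group means, SDs and sizes alone, so headline
#' contrasts reported only as `mean +/- SD` can be verified.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return an `iron_test` result.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  new_test_result(t, df, p, "welch_t", mean1 - mean2)
}

#' Spearman rank correlation with p-value
#'
#' Midrank tie handling; the p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return an `iron_test` with `estimate` = rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
    t <- sign(rho) * Inf
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  new_test_result(t, n - 2, p, "spearman", rho)
}

#' Sample-size-weighted pooled mean
#'
#' Combines per-group means into the total-column mean:
#' `sum(n_i m_i) / sum(n_i)`.
#'
#' @param means per-group means.
#' @param ns per-group sizes.
#' @return scalar pooled mean.
#' @export
pooled_mean_from_groups <- function(means, ns) {
  if (length(means) == 0) stop("empty input")
  stopifnot(length(means) == length(ns), all(ns > 0))
  sum(ns * means) / sum(ns)
}

#' Descriptive table by sex
#'
#' Emits a descriptive-characteristics-shaped table: one row per variable
#' with male, female and total summaries plus the two-group p-value
#' (Welch t, Mann-Whitney or chi-square, routed by catalog type and the
#' skewness rule).
#'
#' @param cohort an `iron_cohort`.
#' @param variables variables to tabulate; defaults to all catalogued
#'   variables present in the data, plus `hic`.
#' @return data frame with columns variable, summary_male, summary_female,
#'   summary_total, p.
#' @export
table_one <- function(cohort, variables = NULL) {
  strata <- stratify_by_sex(cohort)
  d <- cohort$data
  if (is.null(variables))
    variables <- c(intersect(names(cohort$panel), names(d)), "hic")
  fmt_cont <- function(s) {
    if (s$style == "mean_sd")
      sprintf("%.2f ± %.2f", s$mean, s$sd)
    else sprintf("%.2f (%.2f)", s$median, s$iqr)
  }
  rows <- lapply(variables, function(v) {
    sp <- cohort$panel[[v]]
    xm <- strata$male$data[[v]]; xf <- strata$female$data[[v]]
    if (!is.null(sp) && sp$dtype == "categorical") {
      p <- compare_two_groups(xm, xf, "chi_square")$p
      sm <- summarize_categorical(xm); sf <- summarize_categorical(xf)
      st <- summarize_categorical(d[[v]])
      fmt <- function(s) paste(sprintf("%s %.1f%%", s$level, s$percent),
                               collapse = "; ")
      data.frame(variable = v, summary_male = fmt(sm),
                 summary_female = fmt(sf), summary_total = fmt(st), p = p)
    } else {
      skewed <- !is.null(sp) && sp$dist == "lognormal"
      style <- if (skewed) "median_iqr" else "mean_sd"
      p <- compare_two_groups(xm, xf,
                              if (!is.null(sp) && sp$dtype == "binary")
                                "chi_square"
                              else if (skewed) "mann_whitney" else "welch_t")$p
      data.frame(variable = v,
                 summary_male = fmt_cont(summarize_variable(xm, style)),
                 summary_female = fmt_cont(summarize_variable(xf, style)),
                 summary_total = fmt_cont(summarize_variable(d[[v]], style)),
                 p = p)
    }
  })
  do.call(rbind, rows)
}
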