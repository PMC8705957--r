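# Shared fixtures: tiny cohorts, orthonormal designs, and a brute-force
# lasso oracle used to check the coordinate-descent implementation.

# minimal three-variable catalog for hand-built cohorts
tiny_panel <- function() {
  list(
    age = var_spec("age", "normal", male = list(mean = 55, sd = 9),
                   female = list(mean = 55, sd = 9), units = "years"),
    hff = var_spec("hff", "lognormal", male = list(median = 7, iqr = 10),
                   female = list(median = 3.5, iqr = 4.3),
                   log = TRUE, upper = 100, units = "%"),
    alcohol = var_spec("alcohol", "lognormal",
                       male = list(median = 20, iqr = 36),
                       female = list(median = 3, iqr = 13),
                       log = FALSE, upper = 250, units = "g/day")
  )
}

tiny_cohort_df <- function() {
  data.frame(
    id = c("a", "b", "c"),
    sex = c("male", "male", "female"),
    hic_right = c(42.4, 45.0, 39.0),
    hic_left = c(41.1, 44.0, 38.0),
    age = c(60, 50, 55),
    hff = c(7.0, 12.0, 3.0),
    alcohol = c(10, 0, 5),
    stringsAsFactors = FALSE
  )
}

# design with (1/n) X'X = I so the lasso solution is the soft-thresholded
# OLS estimate, coordinate by coordinate
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(n * p), n)))  # orthonormal columns (X'X = I)
  X <- M * sqrt(n)                         # (1/n) X'X = I
  colnames(X) <- paste0("v", seq_len(p))
  X
}

# brute-force minimizer of the lasso objective on a grid, p = 2 only
brute_force_lasso2 <- function(X, y, lambda, lim = 3, step = 2e-4) {
  n <- nrow(X)
  yc <- y - mean(y)
  grid <- seq(-lim, lim, by = step)
  best <- c(NA, NA); bestval <- Inf
  # profile out b2 for each b1 via coordinate minimization on the grid
  for (b1 in grid) {
    r1 <- yc - X[, 1] * b1
    # exact minimizer in b2 given b1 (soft threshold: 1-d problem is exact)
    v2 <- sum(X[, 2]^2) / n
    z <- sum(X[, 2] * r1) / n
    b2 <- sign(z) * max(abs(z) - lambda, 0) / v2
    val <- sum((r1 - X[, 2] * b2)^2) / (2 * n) +
      lambda * (abs(b1) + abs(b2))
    if (val < bestval) { bestval <- val; best <- c(b1, b2) }
  }
  best
}

# KKT conditions for the (1/2n) least-squares lasso at a given solution
kkt_violation <- function(X, y, beta, lambda) {
  n <- nrow(X)
  r <- (y - mean(y)) - X %*% beta
  g <- as.numeric(crossprod(X, r)) / n
  viol <- numeric(length(beta))
  nz <- beta != 0
  viol[nz] <- abs(g[nz] - lambda * sign(beta[nz]))
  viol[!nz] <- pmax(abs(g[!nz]) - lambda, 0)
  max(viol)
}

# small calibrated generator for fast end-to-end runs
small_config <- function(n_male = 60, n_female = 60) {
  generator_config(n_male = n_male, n_female = n_female)
}
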