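make_design <- function(X, y) {
  st <- standardize_like <- list(X = X, X_raw = X, y = y)
  st
}

test_that("lambda_max zeroes all coefficients and has its closed form", {
  # constant outcome
  X <- orthonormal_design(40, 3)
  expect_equal(lambda_max(X, rep(5, 40)), 0)
  # centered single column with (1/n) x'x = 1 and y = x: lambda_max = 1
  x <- X[, 1] - mean(X[, 1])
  x <- matrix(x / sqrt(mean(x^2)), dimnames = list(NULL, "v1"))
  expect_equal(lambda_max(x, as.numeric(x)), 1, tolerance = 1e-12)
  # fitting slightly above lambda_max returns the zero vector
  set.seed(2)
  Xr <- matrix(rnorm(200), 50); colnames(Xr) <- paste0("v", 1:4)
  y <- rnorm(50)
  st <- ironsel:::standardize_matrix(Xr)
  lm0 <- lambda_max(st$X, y)
  b <- fit_lasso(list(X = st$X, y = y), 1.01 * lm0)
  expect_true(all(b == 0))
})

test_that("lasso at lambda = 0 equals ordinary least squares", {
  set.seed(4)
  X <- matrix(rnorm(300), 60); colnames(X) <- paste0("v", 1:5)
  y <- X %*% c(1, -2, 0, 0.5, 0) + rnorm(60)
  st <- ironsel:::standardize_matrix(X)
  b <- fit_lasso(list(X = st$X, y = as.numeric(y)), 0)
  ols <- coef(lm(y ~ st$X))[-1]
  expect_equal(unname(b[, 1]), unname(ols), tolerance = 1e-6)
})

test_that("orthonormal designs give the soft-threshold closed form", {
  for (p in c(2, 5)) {
    X <- orthonormal_design(60, p, seed = p)
    set.seed(p + 10)
    y <- as.numeric(X %*% runif(p, -2, 2) + rnorm(60))
    yc <- y - mean(y)
    bols <- as.numeric(crossprod(X, yc)) / nrow(X)  # (1/n)X'X = I
    for (lam in c(0.05, 0.3, 1)) {
      b <- fit_lasso(list(X = X, y = y), lam)
      expected <- sign(bols) * pmax(abs(bols) - lam, 0)
      expect_equal(unname(b[, 1]), expected, tolerance = 1e-8)
    }
  }
})

test_that("coordinate descent matches brute-force objective minimization (p = 2)", {
  set.seed(9)
  X <- matrix(rnorm(120), 60)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]  # correlated columns
  colnames(X) <- c("a", "b")
  st <- ironsel:::standardize_matrix(X)
  y <- as.numeric(X %*% c(1.2, -0.7) + rnorm(60, 0, 0.5))
  for (lam in c(0.02, 0.2)) {
    b <- fit_lasso(list(X = st$X, y = y), lam)
    bf <- brute_force_lasso2(st$X, y, lam)
    expect_equal(unname(b[, 1]), bf, tolerance = 1e-3)
  }
})

test_that("KKT conditions hold at every returned solution", {
  set.seed(12)
  X <- matrix(rnorm(500), 50); colnames(X) <- paste0("v", 1:10)
  y <- as.numeric(X[, 1] - 0.5 * X[, 3] + rnorm(50))
  st <- ironsel:::standardize_matrix(X)
  grid <- ironsel:::lambda_grid(lambda_max(st$X, y), lasso_config())
  B <- fit_lasso(list(X = st$X, y = y), grid)
  for (l in seq(1, length(grid), by = 7))
    expect_lt(kkt_violation(st$X, y, B[, l], grid[l]), 1e-6)
})

test_that("the active set grows monotonically as the penalty decreases", {
  set.seed(14)
  X <- matrix(rnorm(1500), 100); colnames(X) <- paste0("v", 1:15)
  y <- as.numeric(X %*% c(2, -1.5, 1, rep(0, 12)) + rnorm(100))
  st <- ironsel:::standardize_matrix(X)
  grid <- ironsel:::lambda_grid(lambda_max(st$X, y), lasso_config())
  B <- fit_lasso(list(X = st$X, y = y), grid)
  sizes <- colSums(B != 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("the fitted path agrees with an independent reference implementation", {
  skip_if_not_installed("glmnet")
  set.seed(16)
  n <- 80; p <- 8
  X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("v", 1:p)
  y <- as.numeric(X %*% c(1, -1, 0.5, rep(0, p - 3)) + rnorm(n))
  st <- ironsel:::standardize_matrix(X)
  lams <- c(0.5, 0.2, 0.05, 0.01)
  B <- fit_lasso(list(X = st$X, y = y), lams)
  g <- glmnet::glmnet(st$X, y, lambda = lams, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(as.matrix(g$beta)),
               matrix(as.numeric(B), nrow(B)), tolerance = 1e-4)
})

test_that("cross-validation selects heavy shrinkage for pure noise", {
  set.seed(20)
  X <- matrix(rnorm(200 * 18), 200); colnames(X) <- paste0("v", 1:18)
  y <- rnorm(200)
  st <- ironsel:::standardize_matrix(X)
  grid <- ironsel:::lambda_grid(lambda_max(st$X, y), lasso_config())
  sel <- cv_select_lambda(list(X_raw = X, y = y), lasso_config(), grid = grid)
  # lambda* in the top (heavily penalized) quarter of the grid
  expect_gte(sel$lambda, grid[25])
  b <- fit_lasso(list(X = st$X, y = y), sel$lambda)
  expect_lte(sum(b != 0), 2)
})

test_that("cross-validation keeps a dominant predictor", {
  set.seed(22)
  n <- 300
  X <- matrix(rnorm(n * 10), n); colnames(X) <- paste0("v", 1:10)
  y <- as.numeric(3 * X[, 1] + rnorm(n, 0, 1))  # R^2 ~ 0.9
  st <- ironsel:::standardize_matrix(X)
  grid <- ironsel:::lambda_grid(lambda_max(st$X, y), lasso_config())
  set.seed(1); sel <- cv_select_lambda(list(X_raw = X, y = y), grid = grid)
  b <- fit_lasso(list(X = st$X, y = y), sel$lambda)
  expect_true(b["v1", 1] != 0)
  # determinism: same data and seed give the same lambda*
  set.seed(1); sel2 <- cv_select_lambda(list(X_raw = X, y = y), grid = grid)
  expect_identical(sel$lambda, sel2$lambda)
})

test_that("design building transforms, dummy-codes and standardizes", {
  co <- generate_cohort(small_config(), seed = 25)
  m <- stratify_by_sex(co)$male
  des <- build_design(m)
  expect_true(all(abs(colMeans(des$X)) < 1e-9))
  expect_true(all(abs(apply(des$X, 2, sd) - 1) < 1e-9))
  expect_true(all(c("diabetes_status_prediabetes",
                    "diabetes_status_diabetes") %in% des$column_names))
  expect_false("diabetes_status_normoglycemic" %in% des$column_names)
  expect_true("log_hff" %in% des$column_names)
  # log transform reduces skewness of flagged lognormal variables
  sk <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(sk(des$X_raw[, "log_ggt"])), abs(sk(m$data$ggt)))
  # zero-variance column rejected by name
  m2 <- m
  m2$data$uric_acid <- 1
  expect_error(build_design(m2), "uric_acid")
  # incomplete cases rejected
  m3 <- m
  m3$data$age[1] <- NA
  expect_error(build_design(m3), "complete cases")
})
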