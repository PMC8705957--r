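grs_fixture <- function(n_per_sex = 200, effect = 1.0, resid_sd = 0.1,
                        seed = 1, freq = c(0.3, 0.5)) {
  set.seed(seed)
  pan <- snp_panel(snp_ids = c("s1", "s2"), freq = freq,
                   effect_male = rep(effect, 2),
                   effect_female = rep(effect, 2))
  n <- 2 * n_per_sex
  ids <- sprintf("P%05d", seq_len(n))
  G <- generate_genotypes(pan, n, seed = seed + 1, ids = ids)
  sex <- rep(c("male", "female"), each = n_per_sex)
  hic <- 40 + effect * rowSums(G) + rnorm(n, 0, resid_sd)
  co <- iron_cohort(data.frame(id = ids, sex = sex, hic = hic,
                               stringsAsFactors = FALSE), list())
  list(panel = pan, G = G, cohort = co)
}

test_that("univariate weights recover the per-dosage effect", {
  # univariate slopes are unbiased but see the *other* causal SNP as
  # residual noise (SD ~ 0.71 here), so the slope SE is ~0.015 at
  # n = 5000 per sex; 0.08 is a > 5-SE band
  fx <- grs_fixture(n_per_sex = 5000, effect = 1.0, resid_sd = 0.1, seed = 2)
  w <- estimate_grs_weights(fx$G, fx$cohort)
  expect_true(all(abs(w$male - 1.0) < 0.08))
  expect_true(all(abs(w$female - 1.0) < 0.08))
})

test_that("null SNPs get near-zero weights", {
  # slope SE ~ 0.022 (resid SD 1, n = 5000 per sex); 0.1 is a 4.5-SE band
  fx <- grs_fixture(n_per_sex = 5000, effect = 0, resid_sd = 1, seed = 3)
  w <- estimate_grs_weights(fx$G, fx$cohort)
  expect_true(all(abs(c(w$male, w$female)) < 0.1))
})

test_that("monomorphic SNPs yield weight zero with a warning", {
  fx <- grs_fixture(n_per_sex = 30, seed = 4)
  G <- fx$G
  G[, 2] <- 1  # constant dosage
  warns <- capture_warnings(w <- estimate_grs_weights(G, fx$cohort))
  expect_gte(length(warns), 1)  # one warning per affected stratum
  expect_match(warns, "monomorphic", all = TRUE)
  expect_equal(unname(w$male[2]), 0)
})

test_that("scores are the weighted dosage sums", {
  ids <- c("a", "b", "c")
  co <- iron_cohort(data.frame(id = ids, sex = rep("male", 3),
                               hic = c(40, 41, 42)), list())
  G <- matrix(c(0, 1, 2), 3, 1, dimnames = list(ids, "s1"))
  w <- structure(list(male = c(s1 = 2), female = c(s1 = 2),
                      snp_ids = "s1"), class = "grs_weights")
  sc <- compute_grs(G, w, co)
  expect_equal(sc$grs, c(0, 2, 4))
  # all-zero weights give all-zero scores
  w0 <- structure(list(male = c(s1 = 0), female = c(s1 = 0),
                       snp_ids = "s1"), class = "grs_weights")
  expect_equal(compute_grs(G, w0, co)$grs, rep(0, 3))
})

test_that("scores are invariant to SNP order and affine-equivariant", {
  fx <- grs_fixture(n_per_sex = 50, seed = 6)
  w <- estimate_grs_weights(fx$G, fx$cohort)
  sc <- compute_grs(fx$G, w, fx$cohort)
  # columns are matched by SNP id, so permuting the genotype matrix
  # changes nothing
  Gp <- fx$G[, c(2, 1)]
  expect_equal(compute_grs(Gp, w, fx$cohort)$grs, sc$grs)
  # shifting one SNP's dosages shifts scores by w_j * constant (computed
  # on the raw matrix, ignoring the [0,2] range check via direct sum)
  shift <- cbind(rep(0.5, nrow(fx$G)), 0)
  manual <- as.numeric((fx$G + shift) %*% w$male)
  male_rows <- fx$cohort$data$sex == "male"
  expect_equal(manual[male_rows] - sc$grs[male_rows],
               rep(0.5 * w$male[["s1"]], sum(male_rows)))
})

test_that("quartile contrast yields balanced groups and detects the gradient", {
  fx <- grs_fixture(n_per_sex = 100, effect = 0.65, resid_sd = 1, seed = 7)
  w <- estimate_grs_weights(fx$G, fx$cohort)
  sc <- compute_grs(fx$G, w, fx$cohort)
  qc <- grs_quartile_contrast(sc, fx$cohort)
  for (sx in c("male", "female")) {
    expect_true(all(abs(qc[[sx]]$n - 25) <= 1))
    expect_true(all(diff(qc[[sx]]$means) > 0))  # monotone Q1 -> Q4
    expect_lt(qc[[sx]]$test$p, 0.05)
  }
  # n = 8 per sex: quartiles of size 2
  fx8 <- grs_fixture(n_per_sex = 8, seed = 8)
  w8 <- structure(list(male = c(s1 = 1, s2 = 0.5),
                       female = c(s1 = 1, s2 = 0.5),
                       snp_ids = c("s1", "s2")), class = "grs_weights")
  sc8 <- compute_grs(fx8$G + matrix(runif(32, 0, 1e-6), 16), w8, fx8$cohort)
  qc8 <- grs_quartile_contrast(sc8, fx8$cohort)
  expect_equal(qc8$male$n, rep(2L, 4))
})

test_that("appending the score extends the candidate design by one column", {
  co <- generate_cohort(small_config(), seed = 9)
  pan <- snp_panel()
  G <- generate_genotypes(pan, nrow(co$data), seed = 10, ids = co$data$id)
  w <- estimate_grs_weights(G, co)
  sc <- compute_grs(G, w, co)
  co2 <- append_grs_to_panel(co, sc)
  m1 <- build_design(stratify_by_sex(co)$male)
  m2 <- build_design(stratify_by_sex(co2)$male)
  expect_equal(m2$p, m1$p + 1)
  expect_true("genetic_risk_score" %in% m2$column_names)
  expect_error(append_grs_to_panel(co2, sc), "already has")
  # constant scores are rejected downstream as zero-variance
  sc0 <- sc; sc0$grs <- rep(0, nrow(co$data))
  co3 <- append_grs_to_panel(co, sc0)
  expect_error(build_design(stratify_by_sex(co3)$male),
               "genetic_risk_score")
})
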