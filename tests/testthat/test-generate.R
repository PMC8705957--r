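test_that("generation is bitwise deterministic under a fixed seed", {
  a <- generate_cohort(small_config(), seed = 5)
  b <- generate_cohort(small_config(), seed = 5)
  expect_identical(a$data, b$data)
  c <- generate_cohort(small_config(), seed = 6)
  expect_false(identical(a$data, c$data))
})

test_that("per-sex marginals match the calibrated targets", {
  co <- generate_cohort(generator_config(n_male = 2000, n_female = 2000),
                        seed = 21)
  s <- stratify_by_sex(co)
  pan <- kora_panel()
  # means of normal marginals within 3 SE at n = 2000
  for (v in c("age", "bmi", "hba1c", "uric_acid", "potassium")) {
    for (sx in c("male", "female")) {
      p <- pan[[v]][[sx]]
      x <- s[[sx]]$data[[v]]
      expect_lt(abs(mean(x) - p$mean), 3 * p$sd / sqrt(2000))
    }
  }
  # medians of (untruncated-tail) lognormal marginals near targets
  for (v in c("triglycerides", "ggt", "hff")) {
    for (sx in c("male", "female")) {
      p <- pan[[v]][[sx]]
      x <- s[[sx]]$data[[v]]
      expect_lt(abs(median(x) - p$median) / p$median, 0.1)
    }
  }
  # binary prevalences
  expect_lt(abs(mean(s$male$data$diuretics) - 0.117), 0.03)
  expect_equal(sum(s$female$data$hyperuricemia_treatment), 0)
  # bounds
  expect_true(all(s$male$data$hff >= 0 & s$male$data$hff <= 100))
  expect_true(all(co$data$hic > 0))
})

test_that("zero residual noise and intercept-only model give constant HIC", {
  om <- outcome_model(
    male = list(target_mean = 40, target_sd = 1, coef = numeric(0),
                intercept = 40, resid_sd = 0),
    female = list(target_mean = 40, target_sd = 1, coef = numeric(0),
                  intercept = 40, resid_sd = 0))
  co <- generate_cohort(generator_config(n_male = 20, n_female = 20,
                                         outcome = om), seed = 2)
  expect_equal(co$data$hic, rep(40, 40))
})

test_that("the copula reproduces the target age-HIC rank correlation in women", {
  co <- generate_cohort(generator_config(n_male = 10, n_female = 10000),
                        seed = 31)
  f <- stratify_by_sex(co)$female$data
  rho <- spearman_rho(f$age, f$hic)$estimate
  expect_gt(rho, 0.45)
  expect_lt(rho, 0.51)
})

test_that("OLS on a large low-noise cohort recovers the configured effects", {
  om <- outcome_model(
    male = list(target_mean = 41.8, target_sd = 4.7,
                coef = c(hff = 1.46, alcohol = 0.02, hba1c = -1.44),
                resid_sd = 0.05),
    female = list(target_mean = 39.2, target_sd = 4.1,
                  coef = c(hff = 2.08, alcohol = 0.05, age = 0.22),
                  resid_sd = 0.05))
  co <- generate_cohort(generator_config(n_male = 5000, n_female = 5000,
                                         outcome = om), seed = 41)
  s <- stratify_by_sex(co)
  dm <- s$male$data
  fit <- lm(hic ~ log(hff) + alcohol + hba1c, data = dm)
  expect_equal(unname(coef(fit)[2:4]), c(1.46, 0.02, -1.44),
               tolerance = 0.01)
  df <- s$female$data
  fitf <- lm(hic ~ log(hff) + alcohol + age, data = df)
  expect_equal(unname(coef(fitf)[2:4]), c(2.08, 0.05, 0.22),
               tolerance = 0.01)
})

test_that("correlation targets propagate through the copula", {
  cfg <- generator_config(
    n_male = 8000, n_female = 10,
    correlations = list(list(var1 = "alcohol", var2 = "hff", rho = 0.3)))
  co <- generate_cohort(cfg, seed = 51)
  m <- stratify_by_sex(co)$male$data
  rho <- spearman_rho(m$alcohol, m$hff)$estimate
  expect_lt(abs(rho - 0.3), 0.03)
})

test_that("genotype dosages follow the configured panel", {
  pan <- snp_panel()
  G <- generate_genotypes(pan, 10000, mode = "hard_call", seed = 61)
  expect_true(all(G %in% c(0, 1, 2)))
  expect_equal(unname(colMeans(G) / 2), pan$freq, tolerance = 0.02)
  # freq 0.5 mean-dosage check
  p2 <- snp_panel(snp_ids = c("s1", "s2"), freq = c(0.5, 0.5),
                  effect_male = c(0, 0), effect_female = c(0, 0))
  G2 <- generate_genotypes(p2, 10000, seed = 62)
  expect_true(all(colMeans(G2) > 0.97 & colMeans(G2) < 1.03))
  expect_lt(abs(cor(G2[, 1], G2[, 2])), 0.05)
  # single row, hard-call mode
  G1 <- generate_genotypes(pan, 1, seed = 63)
  expect_equal(dim(G1), c(1L, 4L))
  expect_true(all(G1 %in% c(0, 1, 2)))
  # dosage mode stays in [0, 2]
  Gd <- generate_genotypes(pan, 500, mode = "dosage", seed = 64)
  expect_true(all(Gd >= 0 & Gd <= 2))
  expect_error(snp_panel(freq = c(0, 0.1, 0.2, 0.3)), "strictly inside")
})

test_that("missingness injection flags exactly the requested records", {
  co <- generate_cohort(generator_config(n_male = 233, n_female = 167),
                        seed = 71)
  expect_equal(nrow(co$data), 400)
  co2 <- inject_missingness(co, 47, seed = 72)
  incomplete <- !complete.cases(
    co2$data[, c("hic_right", "hic_left",
                 default_panel(co2$panel)$candidate_names)])
  expect_equal(sum(incomplete), 47)
  expect_identical(inject_missingness(co, 0)$data, co$data)
  expect_error(inject_missingness(co, -1), "non-negative")
  expect_error(inject_missingness(co, 401), "exceeds")
})
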