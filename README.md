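# ironsel

Sex-stratified bootstrap-LASSO stability selection of factors
associated with MRI-derived hepatic iron content (HIC), with a
calibrated synthetic cohort generator, genetic risk scores, adjusted
follow-up regressions, and iron-overload / steatosis classification.

## Background

Hepatic iron content can be quantified non-invasively from multi-echo
MRI as the transverse relaxation rate R2\* = 1/T2\* (s⁻¹), averaged
over the right and left liver lobes; elevated R2\* is the imaging
signature of stored iron. This package re-implements, as a tested and
reusable pipeline, a population-based analysis of such data: all
analyses stratified by sex, candidate covariates (body composition,
blood lipids, glucose markers, renal markers, blood count,
electrolytes, blood pressure, liver enzymes, behavior, medication)
screened by LASSO stability selection, and the selected factors
re-examined in unpenalized adjusted regressions.

Because the original cohort data are access-restricted, the package
ships a generator that emulates the analysis sample (206 men, 147
women) from published sex-stratified summary statistics, so every stage
is runnable and testable offline.

## The model

Per sex stratum, for HIC `y` (s⁻¹) and covariates `x_j` (log-transformed
where flagged as skewed, standardized to unit sample SD):

```
y_i = b0 + sum_j b_j t_j(x_ij) + e_i          (working model)

min_b  (1/2n) || y - b0 - X b ||^2 + lambda ||b||_1    (selection)
```

Stability selection draws B bootstrap resamples (default 1000),
re-standardizes within each resample, tunes `lambda` by 10-fold
cross-validation (CV-minimum rule), fits the LASSO at the selected
penalty, and records each variable's inclusion frequency `pi_j` = share
of resamples with a nonzero coefficient. Variables with `pi_j > 0.20`
(strictly) are flagged relevant. The coordinate-descent kernel is
written in C++ (covariance updates, warm-started paths) and
oracle-tested against closed forms, brute force, KKT conditions, and
`glmnet`.

## Worked example

```r
library(ironsel)

cohort <- generate_cohort(generator_config(), seed = 1)
cohort
#> Cohort of 353 participants ( 206 male / 147 female ), 56 catalogued variables

men <- stratify_by_sex(cohort)$male
pan <- variable_panel(c("hff", "alcohol", "hba1c", "age", "bmi",
                        "uric_acid", "hdl_cholesterol", "triglycerides",
                        "gfr", "hemoglobin"))
fit <- stability_select(men, lasso_config(n_bootstrap = 200, seed = 2),
                        panel = pan)
summary(fit)
#>             variable inclusion_frequency relevant
#> 1              hba1c               0.995     TRUE
#> 2            log_hff               0.990     TRUE
#> 3            alcohol               0.950     TRUE
#> 4                gfr               0.745     TRUE
#> 5                bmi               0.630     TRUE
#> 6          uric_acid               0.560     TRUE
#> 7         hemoglobin               0.545     TRUE
#> 8    hdl_cholesterol               0.535     TRUE
#> 9  log_triglycerides               0.490     TRUE
#> 10               age               0.485     TRUE

fit_adjusted_model(men, "alcohol", adjust = c("age", "hff"))
#> alcohol (age+hff-adjusted): beta = 0.019 [0.003; 0.035], p = 0.02, adj R2 = 0.059 (n = 206)

welch_t_from_summary(41.8, 4.7, 206, 39.2, 4.1, 147)
#> welch_t: statistic = 5.523, df = 337.1, p = 6.66e-08
```

The generator's true male signals (log-HFF, alcohol, HbA1c) top the
ranking. Note the liberality of per-resample CV-minimum tuning: null
variables also accumulate substantial inclusion frequencies, so the
0.20 threshold is best read as a ranking device — see the vignette
(`vignettes/stability-selection.Rmd`) for discussion.

The full pipeline (exclusion filter, descriptive table, per-sex
selection, effect tables, manifest) runs from one configuration:

```r
run_pipeline(run_config(seed = 1, outdir = "results",
                        generator = generator_config(), n_missing = 47))
```

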