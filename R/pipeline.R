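#' Run configuration for the full pipeline
#'
#' Exactly one of `cohort_csv` or `generator` must be given. All
#' randomness (generation, bootstrap resampling, fold splits) derives from
#' the mandatory global `seed`.
#'
#' @param seed global integer seed (mandatory).
#' @param outdir output directory for result tables and the manifest.
#' @param cohort_csv path to a participant CSV (see [load_cohort()]).
#' @param dosage_csv optional path to a dosage CSV (ids in first column).
#' @param generator a [generator_config()] for synthetic input.
#' @param variant one of `"main"`, `"exclude_hff"`, `"ogtt_subsample"`,
#'   `"with_grs"`.
#' @param lasso a [lasso_config()]; `n_bootstrap` can be lowered for
#'   desk-scale runs.
#' @param classifier a [classifier_config()].
#' @param n_missing missingness injected before the exclusion filter when
#'   generating (0 = none).
#' @return list of class `"iron_runconfig"`.
#' @export
run_config <- function(seed, outdir, cohort_csv = NULL, dosage_csv = NULL,
                       generator = NULL,
                       variant = c("main", "exclude_hff", "ogtt_subsample",
                                   "with_grs"),
                       lasso = lasso_config(), classifier = classifier_config(),
                       n_missing = 0) {
  variant <- match.arg(variant)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(cohort_csv) == is.null(generator))
    stop("exactly one of cohort_csv / generator must be given")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 cohort_csv = cohort_csv, dosage_csv = dosage_csv,
                 generator = generator, variant = variant, lasso = lasso,
                 classifier = classifier, n_missing = n_missing),
            class = "iron_runconfig")
}

#' Load a run configuration from YAML
#'
#' Reads a minimal YAML with keys `seed`, `outdir`, `variant`, optional
#' `cohort_csv`/`dosage_csv`, optional `generator: {n_male, n_female}` and
#' optional `lasso: {n_bootstrap, n_folds, ...}` overrides.
#'
#' @param path YAML file path.
#' @return an [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator))
    do.call(generator_config, y$generator) else NULL
  las <- if (!is.null(y$lasso)) do.call(lasso_config, y$lasso)
  else lasso_config()
  run_config(seed = y$seed, outdir = y$outdir,
             cohort_csv = y$cohort_csv, dosage_csv = y$dosage_csv,
             generator = gen,
             variant = if (is.null(y$variant)) "main" else y$variant,
             lasso = las,
             n_missing = if (is.null(y$n_missing)) 0 else y$n_missing)
}

#' Execute the full analysis pipeline
#'
#' Generate or load -> inject missingness (synthetic runs) -> exclusion
#' filter -> sex stratification -> descriptive table -> per-sex bootstrap
#' stability selection -> (variant `with_grs`: genetic risk score,
#' quartile contrast, selection including the score) -> per-sex effect
#' tables. Writes `table1.csv`, `exclusions.csv`, `inclusion_male.csv`,
#' `inclusion_female.csv`, `table2.csv` (men), `table3.csv` (women),
#' optionally `grs_quartiles.csv`, and `manifest.json` to `outdir`.
#' Deterministic under a fixed seed.
#'
#' @param config an [run_config()].
#' @return (invisibly) a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  lcfg <- config$lasso
  lcfg$seed <- config$seed

  cohort <- stage("input", {
    if (!is.null(config$generator)) {
      co <- generate_cohort(config$generator, seed = config$seed)
      if (config$n_missing > 0)
        co <- inject_missingness(co, config$n_missing,
                                 seed = config$seed + 10000L)
      co
    } else load_cohort(config$cohort_csv)
  })

  panel <- switch(config$variant,
    exclude_hff = default_panel(cohort$panel, exclude = "hff"),
    ogtt_subsample = {
      cd <- catalog_df(cohort$panel)
      variable_panel(union(cd$name[cd$candidate],
                           c("two_hour_glucose", "two_hour_insulin")))
    },
    default_panel(cohort$panel))

  analysis <- stage("exclusions", {
    co <- cohort
    if (config$variant == "ogtt_subsample") {
      keep <- is.na(co$data$diabetes_status) |
        co$data$diabetes_status != "diabetes"
      co$data <- co$data[keep, , drop = FALSE]
    }
    apply_exclusions(co, panel)
  })
  excl <- attr(analysis, "exclusions")
  write.csv(excl, file.path(config$outdir, "exclusions.csv"),
            row.names = FALSE)

  strata <- stage("stratify", stratify_by_sex(analysis))
  t1 <- stage("descriptives", table_one(analysis))
  write.csv(t1, file.path(config$outdir, "table1.csv"), row.names = FALSE)

  results <- list(cohort = analysis, table1 = t1, exclusions = excl)

  if (config$variant == "with_grs") {
    gen <- stage("genotypes", {
      pan <- snp_panel()
      G <- generate_genotypes(pan, nrow(analysis$data), mode = "dosage",
                              seed = config$seed + 20000L,
                              ids = analysis$data$id)
      w <- estimate_grs_weights(G, analysis)
      sc <- compute_grs(G, w, analysis)
      qc <- grs_quartile_contrast(sc, analysis)
      list(weights = w, scores = sc, quartiles = qc)
    })
    qrows <- do.call(rbind, lapply(c("male", "female"), function(s)
      data.frame(sex = s, quartile = paste0("Q", 1:4),
                 hic_mean = gen$quartiles[[s]]$means,
                 n = gen$quartiles[[s]]$n,
                 p_q1_vs_q4 = gen$quartiles[[s]]$test$p, row.names = NULL)))
    write.csv(qrows, file.path(config$outdir, "grs_quartiles.csv"),
              row.names = FALSE)
    analysis <- append_grs_to_panel(analysis, gen$scores)
    panel$candidate_names <- c(panel$candidate_names, "genetic_risk_score")
    strata <- stratify_by_sex(analysis)
    results$grs <- gen
  }

  for (s in c("male", "female")) {
    lcfg$seed <- config$seed + if (s == "male") 1000L else 2000L
    fit <- stage(paste0("stability_", s),
                 stability_select(strata[[s]], lcfg, panel = panel))
    write.csv(summary(fit),
              file.path(config$outdir, paste0("inclusion_", s, ".csv")),
              row.names = FALSE)
    rel <- select_relevant(fit)
    results[[paste0("stability_", s)]] <- fit
    if (length(rel)) {
      tab <- stage(paste0("effects_", s),
                   run_effect_table(strata[[s]], rel))
      fn <- if (s == "male") "table2.csv" else "table3.csv"
      write.csv(tab, file.path(config$outdir, fn), row.names = FALSE)
      results[[paste0("effects_", s)]] <- tab
    }
  }

  manifest <- list(
    seed = config$seed, variant = config$variant,
    n_input = nrow(cohort$data), n_analysis = nrow(results$cohort$data),
    n_excluded = nrow(excl),
    n_bootstrap = lcfg$n_bootstrap, n_folds = lcfg$n_folds,
    inclusion_threshold = lcfg$inclusion_threshold,
    package_version = as.character(utils::packageVersion("ironsel")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
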