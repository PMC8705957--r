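#' Variable specification helper
#'
#' Builds one entry of a variable catalog: how a covariate is typed,
#' whether it is log-transformed before regression, its units, and the
#' per-sex marginal distribution used by the synthetic-cohort generator.
#'
#' @param name variable name (column name in the cohort table).
#' @param dist one of `"normal"`, `"lognormal"`, `"bernoulli"`,
#'   `"categorical"`. Determines `dtype`: normal/lognormal are continuous,
#'   bernoulli is binary, categorical is categorical.
#' @param male,female named lists of distribution parameters for each sex:
#'   `mean`, `sd` (normal); `median`, `iqr` (lognormal); `p` (bernoulli);
#'   `probs` (categorical, same order as `levels`).
#' @param log should the variable be natural-log transformed before entering
#'   regression models? Only meaningful for skewed (lognormal) variables.
#' @param units unit string carried as metadata (never converted).
#' @param levels,ref level names and reference level for categoricals.
#' @param upper upper truncation bound for lognormal marginals (e.g. 100 for
#'   a percentage); `Inf` for none.
#' @param candidate should the variable enter the default selection panel?
#' @return a list of class `"iron_varspec"`.
#' @export
var_spec <- function(name, dist, male = NULL, female = NULL, log = FALSE,
                     units = "", levels = NULL, ref = NULL, upper = Inf,
                     candidate = TRUE) {
  dist <- match.arg(dist, c("normal", "lognormal", "bernoulli", "categorical"))
  dtype <- switch(dist, normal = "continuous", lognormal = "continuous",
                  bernoulli = "binary", categorical = "categorical")
  if (dist == "categorical") {
    stopifnot(!is.null(levels), length(levels) >= 2)
    if (is.null(ref)) ref <- levels[[1L]]
    stopifnot(ref %in% levels)
  }
  structure(list(name = name, dist = dist, dtype = dtype, log = log,
                 units = units, levels = levels, ref = ref, upper = upper,
                 candidate = candidate, male = male, female = female),
            class = "iron_varspec")
}

norm_spec <- function(name, m_mean, m_sd, f_mean, f_sd, units = "", ...) {
  var_spec(name, "normal",
           male = list(mean = m_mean, sd = m_sd),
           female = list(mean = f_mean, sd = f_sd), units = units, ...)
}

lnorm_spec <- function(name, m_med, m_iqr, f_med, f_iqr, units = "",
                       upper = Inf, log = TRUE, ...) {
  var_spec(name, "lognormal",
           male = list(median = m_med, iqr = m_iqr),
           female = list(median = f_med, iqr = f_iqr),
           units = units, upper = upper, log = log, ...)
}

bern_spec <- function(name, m_p, f_p, ...) {
  var_spec(name, "bernoulli", male = list(p = m_p), female = list(p = f_p), ...)
}

#' Default covariate catalog calibrated to a population MRI cohort
#'
#' Returns the full marker panel used throughout the package: body
#' composition, blood lipids, glucose metabolism, renal function, blood
#' count, electrolytes, blood pressure, liver parameters, behavioral risk
#' factors and medication flags, with per-sex marginal distributions
#' matching published sex-stratified summary statistics of a
#' population-based whole-body MRI sample (206 men, 147 women).
#'
#' Skewed variables (triglycerides, insulin, GGT, AST, ALT, hepatic fat
#' fraction, CRP, urine albumin, leucocytes, sodium, troponin, alcohol) are
#' modelled lognormal and flagged for natural-log transformation before
#' regression. The hepatic fat fraction is truncated to \[0, 100\] % and
#' alcohol consumption to \[0, 250\] g/day.
#'
#' Variables excluded from the default candidate panel: the two-hour OGTT
#' measures (structurally missing for diagnosed diabetics; used by the OGTT
#' sensitivity variant only), pack-years (structurally missing for
#' never-smokers) and hyperuricemia treatment (zero prevalence in the female
#' stratum, hence a degenerate design column).
#'
#' @return named list of [var_spec()] entries.
#' @export
kora_panel <- function() {
  specs <- list(
    norm_spec("age", 56.0, 9.3, 56.1, 9.0, "years"),
    # body composition
    norm_spec("body_weight", 89.2, 13.4, 72.4, 14.1, "kg"),
    norm_spec("height", 178.01, 6.66, 163.68, 6.58, "cm"),
    norm_spec("bmi", 28.2, 4.1, 27.1, 5.2, "kg/m^2"),
    norm_spec("waist_circumference", 102.7, 11.6, 90.5, 13.4, "cm"),
    norm_spec("hip_circumference", 106.5, 7.1, 105.9, 10.0, "cm"),
    norm_spec("subcutaneous_fat", 7.36, 3.23, 8.72, 3.90, "L"),
    norm_spec("visceral_fat", 5.56, 2.56, 2.79, 1.97, "L"),
    norm_spec("total_fat", 12.92, 5.26, 11.51, 5.43, "L"),
    # blood lipids
    norm_spec("total_cholesterol", 217.5, 38.1, 218.9, 34.7, "mg/dL"),
    norm_spec("hdl_cholesterol", 55.7, 14.8, 71.1, 17.7, "mg/dL"),
    norm_spec("ldl_cholesterol", 142.2, 33.9, 136.3, 32.2, "mg/dL"),
    lnorm_spec("triglycerides", 123.0, 100.5, 89.4, 51.0, "mg/dL"),
    # glucose metabolism
    norm_spec("fasting_glucose", 106.9, 23.5, 98.1, 16.5, "mg/dL"),
    lnorm_spec("fasting_insulin", 11.8, 7.8, 9.3, 5.4, "mU/mL"),
    norm_spec("hba1c", 5.56, 0.83, 5.51, 0.49, "%"),
    lnorm_spec("two_hour_insulin", 46.0, 70.5, 42.0, 39.5, "uU/mL",
               candidate = FALSE),
    norm_spec("two_hour_glucose", 117.4, 44.5, 104.0, 32.9, "mg/dL",
              candidate = FALSE),
    var_spec("diabetes_status", "categorical",
             levels = c("normoglycemic", "prediabetes", "diabetes"),
             ref = "normoglycemic",
             male = list(probs = c(0.573, 0.267, 0.160)),
             female = list(probs = c(0.741, 0.190, 0.068))),
    # renal function
    norm_spec("gfr", 93.6, 16.7, 91.2, 16.9, "mL/min/1.73m^2"),
    norm_spec("uric_acid", 6.33, 1.32, 4.57, 1.11, "mg/dL"),
    norm_spec("creatinine", 0.96, 0.13, 0.77, 0.12, "mg/dL"),
    norm_spec("albumin", 4.41, 0.29, 4.28, 0.27, "g/dL"),
    norm_spec("cystatin_c", 0.89, 0.14, 0.85, 0.17, "mg/L"),
    lnorm_spec("urine_albumin", 6.48, 10.52, 6.22, 8.47, "mg/L"),
    norm_spec("urine_creatinine", 1.75, 0.74, 1.39, 0.82, "g/L"),
    # complete blood count
    norm_spec("hematocrit", 0.43, 0.03, 0.39, 0.03, "L/L"),
    norm_spec("thrombocytes", 221.1, 51.6, 244.5, 52.2, "/nL"),
    norm_spec("erythrocytes", 4.87, 0.37, 4.45, 0.37, "/pL"),
    lnorm_spec("leucocytes", 5.61, 1.93, 5.66, 1.98, "/nL"),
    norm_spec("hemoglobin", 150.4, 10.1, 134.8, 9.8, "g/L"),
    # electrolytes
    norm_spec("potassium", 4.32, 0.31, 4.22, 0.22, "mmol/L"),
    lnorm_spec("sodium", 139.0, 4.0, 139.0, 3.5, "mmol/L"),
    norm_spec("magnesium", 0.85, 0.08, 0.87, 0.08, "mmol/L"),
    norm_spec("phosphate", 0.98, 0.13, 1.12, 0.14, "mmol/L"),
    # blood pressure
    norm_spec("sbp", 125.5, 16.0, 113.0, 14.9, "mmHg"),
    norm_spec("dbp", 77.6, 10.3, 71.8, 8.2, "mmHg"),
    bern_spec("hypertension", 0.374, 0.259),
    # liver parameters
    lnorm_spec("ggt", 35.3, 33.9, 19.6, 17.5, "U/L"),
    lnorm_spec("ast", 24.5, 9.0, 20.0, 8.0, "U/L"),
    lnorm_spec("alt", 31.0, 15.8, 21.0, 12.0, "U/L"),
    lnorm_spec("hff", 7.02, 10.08, 3.53, 4.28, "%", upper = 100),
    # further laboratory values
    norm_spec("alkaline_phosphatase", 65.9, 17.9, 67.6, 23.6, "U/L"),
    lnorm_spec("crp", 1.09, 1.70, 1.26, 2.00, "mg/L"),
    norm_spec("vitamin_d", 24.3, 11.8, 22.2, 11.3, "ng/mL"),
    lnorm_spec("troponin_t", 3.55, 5.20, 1.50, 0.77, "pg/mL"),
    # behavior
    lnorm_spec("alcohol", 20.1, 36.5, 3.1, 12.8, "g/day", upper = 250,
               log = FALSE),
    var_spec("smoking_status", "categorical",
             levels = c("never_smoker", "ex_smoker", "smoker"),
             ref = "never_smoker",
             male = list(probs = c(0.340, 0.461, 0.199)),
             female = list(probs = c(0.422, 0.354, 0.224))),
    bern_spec("physical_inactivity", 0.447, 0.340),
    # medication
    bern_spec("beta_blockers", 0.117, 0.116),
    bern_spec("ace_inhibitors", 0.087, 0.136),
    bern_spec("calcium_antagonists", 0.068, 0.075),
    bern_spec("diuretics", 0.117, 0.136),
    bern_spec("antihypertensives", 0.233, 0.252),
    bern_spec("lipid_lowering_agents", 0.102, 0.102),
    bern_spec("hyperuricemia_treatment", 0.044, 0, candidate = FALSE)
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Flat view of a variable catalog
#'
#' @param panel named list of [var_spec()] entries.
#' @return data frame with one row per variable: name, dtype, dist,
#'   log_transform, units, candidate flag.
#' @export
catalog_df <- function(panel) {
  data.frame(
    name = vapply(panel, `[[`, "", "name"),
    dtype = vapply(panel, `[[`, "", "dtype"),
    dist = vapply(panel, `[[`, "", "dist"),
    log_transform = vapply(panel, `[[`, TRUE, "log"),
    units = vapply(panel, `[[`, "", "units"),
    candidate = vapply(panel, `[[`, TRUE, "candidate"),
    row.names = NULL
  )
}

#' Candidate variable panel
#'
#' The set of variable names entered into the selection stage, optionally
#' with variables forced into every model (none by default).
#'
#' @param candidate_names character vector of candidate variables.
#' @param forced_names variables always retained (disjoint from candidates).
#' @return object of class `"variable_panel"`.
#' @export
variable_panel <- function(candidate_names, forced_names = character()) {
  stopifnot(length(candidate_names) >= 1)
  if (anyDuplicated(candidate_names))
    stop("duplicate candidate names")
  if (length(intersect(candidate_names, forced_names)))
    stop("forced and candidate variable sets must be disjoint")
  structure(list(candidate_names = candidate_names,
                 forced_names = forced_names),
            class = "variable_panel")
}

#' Default candidate panel derived from the catalog
#' @param panel catalog as returned by [kora_panel()].
#' @param exclude variables to drop (e.g. `"hff"` for the HFF-free variant).
#' @return a [variable_panel()].
#' @export
default_panel <- function(panel = kora_panel(), exclude = character()) {
  cd <- catalog_df(panel)
  variable_panel(setdiff(cd$name[cd$candidate], exclude))
}
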