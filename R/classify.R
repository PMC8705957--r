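#' Threshold configuration for clinical classifications
#'
#' Cutoffs for hepatic iron-overload grading (R2*, s^-1) and hepatic
#' steatosis (hepatic fat fraction, percent). The mild cutoff is a strict
#' lower bound (grade "none" at exactly 41 s^-1); the moderate and severe
#' cutoffs are inclusive lower bounds of their grade; the steatosis cutoff
#' is inclusive.
#'
#' @param mild_cutoff,moderate_cutoff,severe_cutoff R2* grade boundaries.
#' @param steatosis_cutoff HFF boundary in percent.
#' @return list of class `"iron_classifier"`.
#' @export
classifier_config <- function(mild_cutoff = 41, moderate_cutoff = 62.5,
                              severe_cutoff = 70.1, steatosis_cutoff = 5.6) {
  stopifnot(mild_cutoff > 0, mild_cutoff < moderate_cutoff,
            moderate_cutoff < severe_cutoff)
  structure(list(mild_cutoff = mild_cutoff, moderate_cutoff = moderate_cutoff,
                 severe_cutoff = severe_cutoff,
                 steatosis_cutoff = steatosis_cutoff),
            class = "iron_classifier")
}

#' Grade hepatic iron overload
#'
#' Maps R2* values onto ordered grades: none (<= 41 s^-1), mild
#' (> 41, < 62.5), moderate ([62.5, 70.1)), severe (>= 70.1). Every
#' positive value maps to exactly one grade.
#'
#' @param hic numeric vector of R2* values, s^-1.
#' @param config a [classifier_config()].
#' @return ordered factor with levels none < mild < moderate < severe.
#' @export
classify_iron_overload <- function(hic, config = classifier_config()) {
  if (any(!is.na(hic) & hic <= 0)) stop("hic must be positive")
  grade <- ifelse(is.na(hic), NA_character_,
           ifelse(hic >= config$severe_cutoff, "severe",
           ifelse(hic >= config$moderate_cutoff, "moderate",
           ifelse(hic > config$mild_cutoff, "mild", "none"))))
  factor(grade, levels = c("none", "mild", "moderate", "severe"),
         ordered = TRUE)
}

#' Classify hepatic steatosis
#'
#' Steatosis iff hepatic fat fraction >= 5.6 % (inclusive).
#'
#' @param hff numeric vector of fat fractions in \[0, 100\].
#' @param config a [classifier_config()].
#' @return factor with levels no_steatosis, steatosis.
#' @export
classify_steatosis <- function(hff, config = classifier_config()) {
  if (any(!is.na(hff) & (hff < 0 | hff > 100)))
    stop("hff must lie in [0, 100] percent")
  factor(ifelse(is.na(hff), NA_character_,
                ifelse(hff >= config$steatosis_cutoff, "steatosis",
                       "no_steatosis")),
         levels = c("no_steatosis", "steatosis"))
}

#' Classify glycemic status
#'
#' Diabetes if physician-diagnosed; otherwise prediabetes or normoglycemia
#' by configurable ADA-style laboratory thresholds (defaults: diabetes at
#' fasting glucose >= 126 mg/dL or 2h glucose >= 200 mg/dL; prediabetes at
#' fasting 100-125 or 2h 140-199).
#'
#' @param fasting_glucose,two_hour_glucose mg/dL; may be `NA`.
#' @param hba1c percent; currently informational only (the operational
#'   definition is glucose-based).
#' @param physician_diagnosis logical flag (must be present).
#' @param thresholds named list of cutoffs.
#' @return factor with levels normoglycemic, prediabetes, diabetes; `NA`
#'   where the diagnosis flag is false and all labs are missing.
#' @export
classify_glycemia <- function(fasting_glucose = NA, two_hour_glucose = NA,
                              hba1c = NA, physician_diagnosis,
                              thresholds = list(fg_dm = 126, fg_pre = 100,
                                                g2h_dm = 200, g2h_pre = 140)) {
  n <- max(length(fasting_glucose), length(two_hour_glucose),
           length(physician_diagnosis))
  fg <- rep_len(fasting_glucose, n)
  g2 <- rep_len(two_hour_glucose, n)
  dx <- rep_len(physician_diagnosis, n)
  if (any(is.na(dx))) stop("physician_diagnosis flag must always be present")
  out <- rep(NA_character_, n)
  out[dx] <- "diabetes"
  lab_dm <- !dx & ((!is.na(fg) & fg >= thresholds$fg_dm) |
                   (!is.na(g2) & g2 >= thresholds$g2h_dm))
  lab_pre <- !dx & !lab_dm &
    ((!is.na(fg) & fg >= thresholds$fg_pre) |
     (!is.na(g2) & g2 >= thresholds$g2h_pre))
  lab_norm <- !dx & !lab_dm & !lab_pre & (!is.na(fg) | !is.na(g2))
  out[lab_dm] <- "diabetes"
  out[lab_pre] <- "prediabetes"
  out[lab_norm] <- "normoglycemic"
  factor(out, levels = c("normoglycemic", "prediabetes", "diabetes"))
}

#' Apply participant-flow exclusions
#'
#' Restricts a cohort to complete cases on the required fields (the HIC
#' lobes, or `hic` where lobes are absent, plus the candidate covariates),
#' recording a per-record exclusion reason. Idempotent.
#'
#' @param cohort an `iron_cohort` (possibly with injected missingness).
#' @param panel a [variable_panel()] giving the required covariates;
#'   defaults to the catalog's candidate set.
#' @return the filtered `iron_cohort`, with the exclusion log (data frame
#'   of id, reason) attached as attribute `"exclusions"`.
#' @export
apply_exclusions <- function(cohort, panel = default_panel(cohort$panel)) {
  d <- cohort$data
  hic_cols <- intersect(c("hic_right", "hic_left"), names(d))
  if (length(hic_cols) == 0) hic_cols <- "hic"
  req <- c(hic_cols, intersect(c(panel$candidate_names, panel$forced_names),
                               names(d)))
  miss <- vapply(seq_len(nrow(d)), function(i) {
    bad <- req[vapply(req, function(v) is.na(d[[v]][i]), TRUE)]
    if (length(bad) == 0) NA_character_
    else paste(bad, collapse = ";")
  }, "")
  keep <- is.na(miss)
  log <- data.frame(id = d$id[!keep], reason = miss[!keep],
                    row.names = NULL)
  if (!any(keep)) warning("exclusion filter removed every participant")
  out <- iron_cohort(d[keep, , drop = FALSE], cohort$panel, validate = FALSE)
  attr(out, "exclusions") <- log
  out
}
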