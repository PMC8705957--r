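#' Cohort container
#'
#' Bundles a participant-level table with its variable catalog. The table
#' must contain `id`, `sex` and the hepatic iron outcome: either `hic`
#' directly or the two lobes `hic_right`/`hic_left` (the outcome is the
#' arithmetic mean of the two lobes, in s^-1).
#'
#' @param data data frame, one row per participant.
#' @param panel variable catalog (named list of [var_spec()]); defaults to
#'   [kora_panel()].
#' @param validate check invariants (positive HIC, HFF in \[0,100\], sex codes,
#'   unique ids, lobe-mean consistency).
#' @return object of class `"iron_cohort"`: list with elements `data` and
#'   `panel`.
#' @export
iron_cohort <- function(data, panel = kora_panel(), validate = TRUE) {
  data <- as.data.frame(data)
  mandatory <- c("id", "sex")
  miss <- setdiff(mandatory, names(data))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  has_lobes <- all(c("hic_right", "hic_left") %in% names(data))
  if (!("hic" %in% names(data)) && !has_lobes)
    stop("missing mandatory columns: hic (or hic_right and hic_left)")
  if (!("hic" %in% names(data)) && has_lobes)
    data$hic <- (data$hic_right + data$hic_left) / 2
  data$id <- as.character(data$id)
  obj <- structure(list(data = data, panel = panel), class = "iron_cohort")
  if (validate) validate_cohort(obj)
  obj
}

validate_cohort <- function(cohort) {
  d <- cohort$data
  if (anyDuplicated(d$id))
    stop("duplicate participant ids: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  bad_sex <- !is.na(d$sex) & !(d$sex %in% c("male", "female"))
  if (any(bad_sex))
    stop("unknown sex code for ids: ", paste(d$id[bad_sex], collapse = ", "))
  if (all(c("hic_right", "hic_left") %in% names(d))) {
    both <- !is.na(d$hic_right) & !is.na(d$hic_left) & !is.na(d$hic)
    dev <- abs(d$hic[both] - (d$hic_right[both] + d$hic_left[both]) / 2)
    if (any(dev > 1e-9))
      stop("hic must equal the mean of the two lobes (max deviation ",
           format(max(dev)), ")")
  }
  if (any(!is.na(d$hic) & d$hic <= 0))
    stop("hic must be positive")
  for (v in intersect(c("hff", "hff_right", "hff_left"), names(d))) {
    x <- d[[v]]
    if (any(!is.na(x) & (x < 0 | x > 100)))
      stop(v, " must lie in [0, 100] percent")
  }
  invisible(cohort)
}

#' @export
print.iron_cohort <- function(x, ...) {
  n <- nrow(x$data)
  tab <- table(factor(x$data$sex, c("male", "female")))
  cat("Cohort of", n, "participants (", tab[["male"]], "male /",
      tab[["female"]], "female ),", length(x$panel), "catalogued variables\n")
  invisible(x)
}

#' @export
dim.iron_cohort <- function(x) dim(x$data)

#' Number of participants
#' @param cohort an `iron_cohort`.
#' @export
n_participants <- function(cohort) nrow(cohort$data)

#' Read a cohort from CSV
#'
#' Reads a UTF-8, comma-separated participant table (header row, one row
#' per participant). Empty cells and `"NA"` are treated as missing.
#' Unparseable numeric cells become missing with a warning, never silently
#' dropped rows.
#'
#' @param path CSV file path.
#' @param panel variable catalog; columns present in the file but absent
#'   from the catalog are kept as-is.
#' @return an [iron_cohort()].
#' @export
load_cohort <- function(path, panel = kora_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), check.names = FALSE)
  for (v in names(raw)) {
    sp <- panel[[v]]
    if (is.null(sp)) next
    if (sp$dtype %in% c("continuous", "binary")) {
      val <- suppressWarnings(as.numeric(raw[[v]]))
      newly <- is.na(val) & !is.na(raw[[v]])
      if (any(newly))
        warning(sum(newly), " unparseable values in '", v,
                "' set to missing")
      raw[[v]] <- val
    } else if (sp$dtype == "categorical") {
      bad <- !is.na(raw[[v]]) & !(raw[[v]] %in% sp$levels)
      if (any(bad))
        warning(sum(bad), " unknown levels in '", v, "' set to missing")
      raw[[v]][bad] <- NA
    }
  }
  iron_cohort(raw, panel)
}

#' Write a cohort to CSV
#'
#' Values are written with 12 significant digits so that a
#' write/load round trip is the identity up to numeric formatting.
#'
#' @param cohort an `iron_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  d <- cohort$data
  for (v in names(d))
    if (is.numeric(d[[v]])) d[[v]] <- signif(d[[v]], 12)
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split a cohort into male and female strata
#'
#' All downstream analyses are stratified by sex; this returns disjoint
#' strata whose union is the input, with row order preserved.
#'
#' @param cohort an `iron_cohort`.
#' @return list with elements `male` and `female`, each an `iron_cohort`.
#' @export
stratify_by_sex <- function(cohort) {
  d <- cohort$data
  if (any(is.na(d$sex)))
    stop("sex missing for ids: ", paste(d$id[is.na(d$sex)], collapse = ", "))
  bad <- !(d$sex %in% c("male", "female"))
  if (any(bad))
    stop("unknown sex code for ids: ", paste(d$id[bad], collapse = ", "))
  list(
    male = iron_cohort(d[d$sex == "male", , drop = FALSE], cohort$panel,
                       validate = FALSE),
    female = iron_cohort(d[d$sex == "female", , drop = FALSE], cohort$panel,
                         validate = FALSE)
  )
}
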