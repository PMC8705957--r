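#' Sex-specific SNP weights from univariate regressions
#'
#' For each SNP and each sex stratum, the weight is the slope of an
#' intercept-only-adjusted ordinary least squares regression of hepatic
#' iron content on allele dosage (univariate: no covariates). Monomorphic
#' SNPs within a stratum get weight 0 with a warning.
#'
#' @param genotypes n x m dosage matrix (values in \[0, 2\], rownames = ids).
#' @param cohort an `iron_cohort` with `hic` present; ids must match the
#'   genotype rownames.
#' @return list of class `"grs_weights"` with numeric vectors `male` and
#'   `female` (one weight per SNP, s^-1 per dosage unit).
#' @export
estimate_grs_weights <- function(genotypes, cohort) {
  d <- cohort$data
  if (is.null(rownames(genotypes)))
    stop("genotype matrix must carry participant ids as rownames")
  if (!all(d$id %in% rownames(genotypes)))
    stop("genotypes missing for some cohort ids")
  G <- genotypes[d$id, , drop = FALSE]
  if (any(G < 0 | G > 2)) stop("dosages must lie in [0, 2]")
  weights_for <- function(rows) {
    if (sum(rows) < 10)
      stop("need at least 10 participants per sex stratum")
    y <- d$hic[rows]
    apply(G[rows, , drop = FALSE], 2, function(g) {
      if (sd(g) == 0) {
        warning("monomorphic SNP in stratum; weight set to 0")
        return(0)
      }
      unname(coef(lm(y ~ g))[2L])
    })
  }
  structure(list(male = weights_for(d$sex == "male"),
                 female = weights_for(d$sex == "female"),
                 snp_ids = colnames(genotypes)),
            class = "grs_weights")
}

#' Weighted allele-dosage genetic risk score
#'
#' Per participant: the sum over SNPs of the sex-specific weight times the
#' allele dosage, `GRS_i = sum_j w_j(sex_i) * d_ij`.
#'
#' @param genotypes dosage matrix with ids as rownames.
#' @param weights a `grs_weights` object.
#' @param cohort an `iron_cohort` (supplies each participant's sex).
#' @return data frame with columns id, sex, grs.
#' @export
compute_grs <- function(genotypes, weights, cohort) {
  d <- cohort$data
  if (!all(d$id %in% rownames(genotypes)))
    stop("genotypes missing for some cohort ids")
  G <- genotypes[d$id, weights$snp_ids, drop = FALSE]
  grs <- numeric(nrow(d))
  for (s in c("male", "female")) {
    rows <- d$sex == s
    if (any(rows))
      grs[rows] <- as.numeric(G[rows, , drop = FALSE] %*% weights[[s]])
  }
  data.frame(id = d$id, sex = d$sex, grs = grs, stringsAsFactors = FALSE)
}

#' Quartile contrast of hepatic iron across the genetic risk score
#'
#' Sex-stratified quartile assignment (type-7 cut points, ties broken by
#' midrank then stable id order so groups differ in size by at most one),
#' per-quartile HIC means, and a Welch t-test of the lowest vs the highest
#' quartile within each sex.
#'
#' @param scores data frame from [compute_grs()].
#' @param cohort matching `iron_cohort`.
#' @return list with per-sex elements, each containing `means` (named Q1-Q4
#'   HIC means), `n` (per-quartile sizes) and `test` (Q1 vs Q4 Welch
#'   `iron_test`), plus a `quartile` factor aligned with `scores`.
#' @export
grs_quartile_contrast <- function(scores, cohort) {
  d <- cohort$data
  stopifnot(identical(scores$id, d$id))
  quart <- rep(NA_integer_, nrow(d))
  out <- list()
  for (s in c("male", "female")) {
    rows <- which(d$sex == s)
    if (length(rows) < 8)
      stop("need at least 8 participants per sex for quartiles")
    g <- scores$grs[rows]
    # midrank-based assignment keeps groups within one of each other even
    # under ties; stable order by id for exact ties
    rk <- rank(g, ties.method = "first")
    q <- cut(rk, breaks = quantile(rk, probs = seq(0, 1, 0.25), type = 7),
             include.lowest = TRUE, labels = FALSE)
    if (length(unique(q)) < 4)
      stop("ties collapse a quartile; scores are too discrete")
    quart[rows] <- q
    hic <- d$hic[rows]
    means <- tapply(hic, q, mean)
    ns <- as.integer(table(q))
    tst <- compare_two_groups(hic[q == 1], hic[q == 4], "welch_t")
    out[[s]] <- list(means = setNames(as.numeric(means),
                                      paste0("Q", 1:4)),
                     n = ns, test = tst)
  }
  out$quartile <- factor(paste0("Q", quart), levels = paste0("Q", 1:4))
  out
}

#' Append the continuous genetic risk score to the candidate panel
#'
#' Adds a `genetic_risk_score` column to the cohort (and to its catalog as
#' a continuous, untransformed candidate variable) so the score enters the
#' variable-selection stage alongside the other markers.
#'
#' @param cohort an `iron_cohort`.
#' @param scores data frame from [compute_grs()].
#' @return the augmented `iron_cohort`.
#' @export
append_grs_to_panel <- function(cohort, scores) {
  if ("genetic_risk_score" %in% names(cohort$data))
    stop("cohort already has a genetic_risk_score column")
  stopifnot(identical(scores$id, cohort$data$id))
  cohort$data$genetic_risk_score <- scores$grs
  cohort$panel$genetic_risk_score <-
    var_spec("genetic_risk_score", "normal",
             male = list(mean = NA, sd = NA),
             female = list(mean = NA, sd = NA),
             units = "s^-1")
  cohort
}
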