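#' Variant QC thresholds
#'
#' Bundles the thresholds applied by \code{\link{apply_variant_qc}}. Defaults
#' follow standard dairy-cattle practice: array (chip) genotypes are kept at
#' MAF > 1\% and Hardy-Weinberg P > 1e-4, while imputed sequence variants are
#' kept at MAF >= 0.005 and Minimac-style imputation R-squared >= 0.20.
#'
#' @param min_maf MAF floor for the sequence-variant stage (kept when
#'   \code{maf >= min_maf}).
#' @param min_imputation_r2 imputation quality floor for the sequence stage.
#' @param chip_min_maf MAF floor for the chip stage (kept when
#'   \code{maf > chip_min_maf}, strict, mirroring "MAF > 1\%").
#' @param hwe_p_floor Hardy-Weinberg exact-fit floor for the chip stage
#'   (kept when the chi-square P-value exceeds it).
#' @return a list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_maf = 0.005, min_imputation_r2 = 0.20,
                          chip_min_maf = 0.01, hwe_p_floor = 1e-4) {
  th <- list(min_maf = min_maf, min_imputation_r2 = min_imputation_r2,
             chip_min_maf = chip_min_maf, hwe_p_floor = hwe_p_floor)
  if (any(unlist(th) < 0 | unlist(th) > 1)) {
    stop("all QC thresholds must lie in [0, 1]")
  }
  structure(th, class = "qc_thresholds")
}

#' Apply variant quality control
#'
#' Two stages are available, mirroring the two genotype sources of a
#' chip-plus-imputation design:
#' \describe{
#'   \item{\code{"chip_qc"}}{array-call QC: folded MAF strictly above
#'     \code{chip_min_maf} and a 1-df Hardy-Weinberg chi-square test on
#'     hard-called genotypes (dosages rounded to the nearest integer) with
#'     P > \code{hwe_p_floor}. Rounding is confined to this stage; imputed
#'     sequence dosages are never hard-called.}
#'   \item{\code{"sequence_filter"}}{imputed-variant filter: folded MAF at
#'     least \code{min_maf} and imputation R-squared at least
#'     \code{min_imputation_r2}. Variants without an R-squared value pass
#'     that criterion (no evidence against them).}
#' }
#'
#' @param dm a \code{\link{dosage_matrix}}.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @param stage \code{"chip_qc"} or \code{"sequence_filter"}.
#' @return list with \code{dm} (surviving variants, original order) and
#'   \code{report}, a data.frame of removal counts per criterion (a variant
#'   failing several criteria is counted under each).
#' @export
apply_variant_qc <- function(dm, thresholds = qc_thresholds(),
                             stage = c("sequence_filter", "chip_qc")) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (!is.character(stage) || !all(stage %in% c("sequence_filter", "chip_qc"))) {
    stop("unknown QC stage: ", paste(stage, collapse = ", "))
  }
  stage <- match.arg(stage)
  maf <- folded_maf(dm)
  if (stage == "chip_qc") {
    fail_maf <- maf <= thresholds$chip_min_maf
    hwe_p <- hwe_test(dm)
    fail_hwe <- hwe_p <= thresholds$hwe_p_floor
    keep <- !(fail_maf | fail_hwe)
    report <- data.frame(criterion = c("maf", "hwe"),
                         removed = c(sum(fail_maf), sum(fail_hwe)))
  } else {
    fail_maf <- maf < thresholds$min_maf
    r2 <- dm$variants$imputation_r2
    fail_r2 <- !is.na(r2) & r2 < thresholds$min_imputation_r2
    keep <- !(fail_maf | fail_r2)
    report <- data.frame(criterion = c("maf", "imputation_r2"),
                         removed = c(sum(fail_maf), sum(fail_r2)))
  }
  list(dm = dm[, which(keep)], report = report)
}

#' Hardy-Weinberg chi-square test on hard-called genotypes
#'
#' 1-df goodness-of-fit test of the genotype classes obtained by rounding
#' dosages to the nearest integer against Hardy-Weinberg proportions.
#'
#' @param dm a \code{\link{dosage_matrix}}.
#' @return numeric vector of P-values, one per variant. Monomorphic
#'   variants return 1.
#' @export
hwe_test <- function(dm) {
  g <- round(dm$dosages)
  if (ncol(g) == 0) return(numeric(0))
  n <- nrow(g)
  n2 <- colSums(g == 2)
  n1 <- colSums(g == 1)
  n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  exp0 <- n * (1 - p)^2
  exp1 <- n * 2 * p * (1 - p)
  exp2 <- n * p^2
  chisq <- mapply(function(o0, o1, o2, e0, e1, e2) {
    e <- c(e0, e1, e2); o <- c(o0, o1, o2)
    ok <- e > 0
    sum((o[ok] - e[ok])^2 / e[ok])
  }, n0, n1, n2, exp0, exp1, exp2)
  pv <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  pv[p == 0 | p == 1] <- 1
  unname(pv)
}
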