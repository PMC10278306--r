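#' Construct a dosage matrix
#'
#' The central genotype container of the package: an \code{n_samples x
#' n_variants} matrix of ALT-allele dosages in \code{[0, 2]} together with
#' per-variant and per-sample metadata. All downstream stages (genomic
#' relationship matrices, association scans, LD computation, the QTL caller)
#' consume this object.
#'
#' Missing dosages are not supported: the intended inputs are fully imputed
#' genotypes, and the constructor fails loudly on \code{NA} rather than
#' imputing silently.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns,
#'   values in \code{[0, 2]}.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} and optionally \code{maf} and
#'   \code{imputation_r2}. One row per column of \code{dosages}. Positions
#'   are 1-based base pairs (VCF convention).
#' @param samples data.frame with column \code{sample_id} and optionally
#'   \code{population}, \code{sex} (all-female cohorts use \code{"F"}) and
#'   \code{sire}. One row per row of \code{dosages}. May also be a character
#'   vector of sample ids.
#' @return an object of class \code{dosage_matrix} with elements
#'   \code{dosages}, \code{variants}, \code{samples}.
#' @details The minor allele frequency is the folded ALT frequency
#'   \code{min(p, 1 - p)} with \code{p = mean(dosage) / 2}. When a
#'   \code{maf} column is supplied it is checked against the dosages (within
#'   1e-6); when absent it is recomputed from the data. The tested/effect
#'   allele is ALT throughout the package.
#' @export
dosage_matrix <- function(dosages, variants, samples) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.character(samples)) samples <- data.frame(sample_id = samples)
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  if (anyNA(dosages)) {
    stop("dosage matrix contains missing values; inputs must be fully imputed")
  }
  if (nrow(samples) != nrow(dosages)) {
    stop("sample metadata rows (", nrow(samples),
         ") do not match dosage rows (", nrow(dosages), ")")
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant metadata rows (", nrow(variants),
         ") do not match dosage columns (", ncol(dosages), ")")
  }
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant id(s): ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample id(s)")
  }
  if (any(dosages < 0 | dosages > 2)) {
    bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)[1, ]
    stop("dosage outside [0, 2] for sample '", samples$sample_id[bad[1]],
         "', variant '", variants$id[bad[2]], "'")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1 (1-based bp)")
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  maf <- folded_maf(dosages)
  if (is.null(variants$maf) || all(is.na(variants$maf))) {
    variants$maf <- maf
  } else {
    chk <- !is.na(variants$maf)
    if (any(abs(variants$maf[chk] - maf[chk]) > 1e-6)) {
      bad <- variants$id[chk][which(abs(variants$maf[chk] - maf[chk]) > 1e-6)[1]]
      stop("stored MAF disagrees with dosages for variant '", bad, "'")
    }
    variants$maf[!chk] <- maf[!chk]
  }
  if (is.null(variants$imputation_r2)) variants$imputation_r2 <- NA_real_
  if (any(!is.na(variants$imputation_r2) &
          (variants$imputation_r2 < 0 | variants$imputation_r2 > 1))) {
    stop("imputation_r2 outside [0, 1]")
  }
  if (is.null(samples$sex)) samples$sex <- "F"
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "dosage_matrix")
}

#' Folded minor allele frequency from dosages
#'
#' @param dosages numeric matrix of dosages (samples x variants) or a
#'   \code{dosage_matrix}.
#' @return numeric vector \code{min(p, 1 - p)} per variant, where \code{p}
#'   is the ALT allele frequency \code{mean(dosage)/2}.
#' @export
folded_maf <- function(dosages) {
  if (inherits(dosages, "dosage_matrix")) dosages <- dosages$dosages
  p <- unname(colMeans(dosages)) / 2
  pmin(p, 1 - p)
}

#' ALT allele frequency from dosages
#' @param dm a \code{dosage_matrix}
#' @return numeric vector of unfolded ALT frequencies.
#' @export
alt_freq <- function(dm) {
  colMeans(dm$dosages) / 2
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  if (!is.null(x$samples$population)) {
    cat("  populations:",
        paste(names(table(x$samples$population)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Subset a dosage matrix
#'
#' @param x a \code{dosage_matrix}
#' @param i sample index (integer, logical, or sample ids)
#' @param j variant index (integer, logical, or variant ids)
#' @param ... ignored
#' @return a \code{dosage_matrix} restricted to the selected samples/variants.
#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(i)) stop("unknown sample id in subset")
  if (anyNA(j)) stop("unknown variant id in subset")
  v <- x$variants[j, , drop = FALSE]
  v$maf <- NULL  # recomputed from the subset cohort
  dosage_matrix(x$dosages[i, j, drop = FALSE], v,
                x$samples[i, , drop = FALSE])
}
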