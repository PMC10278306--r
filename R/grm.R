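#' Compute a genomic relationship matrix
#'
#' VanRaden-style GRM from allele dosages over an arbitrary SNP subset
#' (autosomal, X, or combined):
#' \deqn{G_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' where \eqn{p_i} is the ALT allele frequency of SNP \eqn{i} computed from
#' the analyzed cohort itself, and \eqn{m} the number of subset SNPs.
#' Diagonal entries use the same estimator as off-diagonals, which makes
#' \eqn{G = Z Z'/m} with standardized \eqn{Z} and guarantees positive
#' semi-definiteness; the difference from the GCTA diagonal variant is
#' O(1/m). All analyzed animals are female, so X-linked SNPs are treated
#' exactly like autosomal ones (two active copies, no dosage-compensation
#' coding).
#'
#' @param dm a \code{\link{dosage_matrix}} (QC'd upstream; no MAF re-filter
#'   happens here).
#' @param snp_subset variant ids, or integer/logical index over the columns
#'   of \code{dm}; \code{NULL} uses all variants.
#' @param label snp-set label stored in the result (e.g. \code{"autosomal"},
#'   \code{"X"}).
#' @return object of class \code{grm_matrix}: list with \code{values}
#'   (symmetric n x n matrix), \code{samples}, \code{n_snps},
#'   \code{snp_ids}, \code{snp_set_label}.
#' @export
compute_grm <- function(dm, snp_subset = NULL, label = "all") {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(dm$dosages))
  if (is.character(snp_subset)) {
    idx <- match(snp_subset, dm$variants$id)
    if (anyNA(idx)) stop("unknown variant id(s) in snp_subset: ",
                         paste(snp_subset[is.na(idx)], collapse = ", "))
  } else if (is.logical(snp_subset)) {
    idx <- which(snp_subset)
  } else {
    idx <- as.integer(snp_subset)
  }
  if (length(idx) == 0) stop("snp_subset is empty")
  X <- dm$dosages[, idx, drop = FALSE]
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic SNP(s) in GRM subset: ",
         paste(dm$variants$id[idx][mono], collapse = ", "))
  }
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / length(idx)
  structure(list(values = G, samples = dm$samples$sample_id,
                 n_snps = length(idx),
                 snp_ids = dm$variants$id[idx], snp_set_label = label),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat("grm_matrix '", x$snp_set_label, "': ", length(x$samples),
      " samples, ", x$n_snps, " SNPs\n", sep = "")
  invisible(x)
}

#' Write a GRM in text format
#'
#' Two files mirroring the information content of GCTA's text GRM:
#' \code{<prefix>.grm.ids} (one sample id per line) and
#' \code{<prefix>.grm.tsv} (lower triangle including the diagonal, columns
#' \code{i}, \code{j}, \code{n_snps}, \code{value} with 1-based indices into
#' the id file).
#'
#' @param grm a \code{grm_matrix}.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm_matrix"))
  writeLines(grm$samples, paste0(prefix, ".grm.ids"))
  n <- length(grm$samples)
  lt <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  dt <- data.table::data.table(i = lt[, 1], j = lt[, 2],
                               n_snps = grm$n_snps,
                               value = grm$values[lt])
  data.table::fwrite(dt, paste0(prefix, ".grm.tsv"), sep = "\t")
  invisible(prefix)
}

#' Read a GRM written by \code{\link{write_grm}}
#'
#' @param prefix path prefix used at write time.
#' @param label snp-set label for the reconstructed object.
#' @return a \code{grm_matrix} (without \code{snp_ids}, which the text
#'   format does not carry).
#' @export
read_grm <- function(prefix, label = "all") {
  ids <- readLines(paste0(prefix, ".grm.ids"))
  dt <- data.table::fread(paste0(prefix, ".grm.tsv"), sep = "\t")
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(dt$i, dt$j)] <- dt$value
  G[cbind(dt$j, dt$i)] <- dt$value
  structure(list(values = G, samples = ids, n_snps = dt$n_snps[1],
                 snp_ids = NULL, snp_set_label = label),
            class = "grm_matrix")
}
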