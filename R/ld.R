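#' Pairwise linkage disequilibrium (r2) within a chromosome
#'
#' Squared Pearson correlation of allele dosages for all intra-chromosome
#' variant pairs up to a maximum distance, after excluding low-MAF variants.
#' The r2 statistic is symmetric in the pair and invariant to allele-coding
#' flips.
#'
#' @param dm a \code{\link{dosage_matrix}}.
#' @param chrom chromosome to analyze.
#' @param max_dist_bp maximum pair distance in bp (default 10 Mb).
#' @param min_maf folded-MAF exclusion threshold; variants with MAF below it
#'   are excluded (default 0.01).
#' @param one_daughter_per_sire if \code{TRUE} and the sample metadata has a
#'   \code{sire} column, one daughter per sire is sampled (deterministically,
#'   the first) before computing LD, minimizing the accumulation of shared
#'   paternal haplotypes; when no sire information is present all samples
#'   are used and a message says so.
#' @return data.frame with columns \code{pos_i, pos_j, dist, r2}
#'   (\code{pos_i < pos_j}); empty (with a warning) when no variants
#'   survive the MAF filter.
#' @export
pairwise_r2 <- function(dm, chrom, max_dist_bp = 1e7, min_maf = 0.01,
                        one_daughter_per_sire = FALSE) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (!chrom %in% dm$variants$chrom) stop("chromosome not present: ", chrom)
  if (one_daughter_per_sire) {
    if (is.null(dm$samples$sire)) {
      message("pairwise_r2: no sire column in sample metadata; ",
              "using all samples")
    } else {
      keep <- !duplicated(dm$samples$sire)
      dm <- dm[which(keep), ]
    }
  }
  sel <- which(dm$variants$chrom == chrom & folded_maf(dm) >= min_maf)
  if (!length(sel)) {
    warning("no variants on chromosome ", chrom, " pass the MAF filter")
    return(data.frame(pos_i = numeric(), pos_j = numeric(),
                      dist = numeric(), r2 = numeric()))
  }
  sel <- sel[order(dm$variants$pos[sel])]
  pos <- dm$variants$pos[sel]
  R <- suppressWarnings(stats::cor(dm$dosages[, sel, drop = FALSE]))
  pr <- which(upper.tri(R), arr.ind = TRUE)
  dist <- pos[pr[, 2]] - pos[pr[, 1]]
  ok <- dist <= max_dist_bp & !is.na(R[pr])
  data.frame(pos_i = pos[pr[ok, 1]], pos_j = pos[pr[ok, 2]],
             dist = dist[ok], r2 = R[pr][ok]^2)
}

#' Default LD distance bins
#'
#' 0-10 kb, then log-spaced up to the maximum distance.
#'
#' @param max_dist_bp maximum distance covered.
#' @param n_bins number of log-spaced bins after the first.
#' @return numeric vector of bin edges.
#' @export
default_ld_bins <- function(max_dist_bp = 1e7, n_bins = 12) {
  c(0, round(exp(seq(log(1e4), log(max_dist_bp), length.out = n_bins))))
}

#' Distance-binned LD decay
#'
#' Unweighted mean of pairwise r2 within half-open distance bins
#' \code{[lo, hi)}.
#'
#' @param pairs data.frame from \code{\link{pairwise_r2}}.
#' @param bin_edges strictly increasing numeric vector of bin edges.
#' @return data.frame with one row per bin: \code{distance_lo_bp,
#'   distance_hi_bp, mean_r2, n_pairs}; empty bins carry \code{n_pairs = 0}
#'   and \code{NA} mean.
#' @export
bin_decay <- function(pairs, bin_edges = default_ld_bins()) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1
  idx <- findInterval(pairs$dist, bin_edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > nb] <- NA
  mean_r2 <- rep(NA_real_, nb)
  n_pairs <- integer(nb)
  if (nrow(pairs)) {
    agg_n <- tapply(pairs$r2, factor(idx, levels = seq_len(nb)), length)
    agg_m <- tapply(pairs$r2, factor(idx, levels = seq_len(nb)), mean)
    n_pairs <- as.integer(ifelse(is.na(agg_n), 0L, agg_n))
    mean_r2 <- as.numeric(agg_m)
  }
  data.frame(distance_lo_bp = bin_edges[-length(bin_edges)],
             distance_hi_bp = bin_edges[-1],
             mean_r2 = mean_r2, n_pairs = n_pairs)
}
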