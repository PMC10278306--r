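#' Fixed-effects inverse-variance meta-analysis of association scans
#'
#' Combines per-variant effects across populations under the fixed-effects
#' assumption (the true allele effect is shared), weighting each study
#' estimate by the inverse of its error variance (the METAL "STDERR"
#' scheme):
#' \deqn{w_i = 1/se_i^2,\quad b_{meta} = \frac{\sum w_i b_i}{\sum w_i},\quad
#'   se_{meta} = \left(\sum w_i\right)^{-1/2}}
#' with \code{z = b_meta/se_meta} and a two-sided normal P-value. A
#' sample-size-weighted z-score scheme (METAL "SAMPLESIZE") is available for
#' comparison; it produces no pooled effect estimate.
#'
#' Variants are matched across studies by (chrom, pos, allele pair), not by
#' id string. A study whose REF/ALT coding is swapped relative to the first
#' study carrying the variant is flipped (\code{b -> -b},
#' \code{freq -> 1 - freq}); variants whose alleles cannot be reconciled by
#' flipping are dropped with a warning. Variants present in a subset of
#' studies are combined over that subset, with \code{"?"} in the direction
#' string for absent studies.
#'
#' @param scans list of \code{scan_result} objects (or data.frames with the
#'   \code{stats} columns plus \code{ref}/\code{alt} allele columns), one
#'   per population, in a fixed study order.
#' @param dms list of \code{\link{dosage_matrix}} objects parallel to
#'   \code{scans}, used for allele metadata when \code{scans} are
#'   \code{scan_result}s.
#' @param scheme \code{"stderr"} (default, inverse-variance) or
#'   \code{"samplesize"}.
#' @return data.frame of class \code{meta_result}, sorted by (chrom, pos):
#'   \code{id, chrom, pos, ref, alt, b_meta, se_meta, z, p, neglog10p,
#'   n_studies, n, direction}.
#' @export
fixed_effects_meta <- function(scans, dms = NULL,
                               scheme = c("stderr", "samplesize")) {
  scheme <- match.arg(scheme)
  if (!length(scans)) stop("need at least one scan")
  tabs <- lapply(seq_along(scans), function(k) {
    s <- scans[[k]]
    if (inherits(s, "scan_result")) {
      st <- s$stats
      if (!is.null(dms)) {
        v <- dms[[k]]$variants[match(st$id, dms[[k]]$variants$id), ]
        st$ref <- v$ref
        st$alt <- v$alt
      } else {
        st$alt <- st$effect_allele
        st$ref <- "?"
      }
      st
    } else {
      as.data.frame(s)
    }
  })
  n_stud <- length(tabs)
  # reference allele orientation: first study that carries the variant
  key <- function(t) paste(t$chrom, t$pos)
  ref_tab <- NULL
  for (t in tabs) {
    t0 <- t[, c("chrom", "pos", "ref", "alt")]
    ref_tab <- if (is.null(ref_tab)) t0 else
      rbind(ref_tab, t0[!(key(t0) %in% key(ref_tab)), ])
  }
  rk <- key(ref_tab)
  B <- SE <- Freq <- matrix(NA_real_, nrow(ref_tab), n_stud)
  Nmat <- matrix(0, nrow(ref_tab), n_stud)
  dropped <- character(0)
  for (k in seq_len(n_stud)) {
    t <- tabs[[k]]
    i <- match(key(t), rk)
    same <- t$ref == ref_tab$ref[i] & t$alt == ref_tab$alt[i]
    flip <- t$ref == ref_tab$alt[i] & t$alt == ref_tab$ref[i]
    bad <- !(same | flip)
    if (any(bad)) {
      dropped <- union(dropped, rk[i[bad]])
    }
    use <- which(same | flip)
    if (length(use)) {
      sgn <- ifelse(flip, -1, 1)
      B[cbind(i[use], k)] <- (sgn * t$b)[use]
      SE[cbind(i[use], k)] <- t$se[use]
      Freq[cbind(i[use], k)] <- ifelse(flip, 1 - t$freq, t$freq)[use]
      Nmat[cbind(i[use], k)] <- t$n[use]
    }
  }
  if (length(dropped)) {
    keep <- !(rk %in% dropped)
    warning("dropping ", length(dropped),
            " variant(s) with irreconcilable alleles across studies")
    ref_tab <- ref_tab[keep, ]; B <- B[keep, , drop = FALSE]
    SE <- SE[keep, , drop = FALSE]; Nmat <- Nmat[keep, , drop = FALSE]
  }
  if (nrow(ref_tab) == 0) {
    out <- data.frame(id = character(), chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      b_meta = numeric(), se_meta = numeric(), z = numeric(),
                      p = numeric(), neglog10p = numeric(),
                      n_studies = integer(), n = numeric(),
                      direction = character())
    class(out) <- c("meta_result", "data.frame")
    return(out)
  }
  direction <- apply(B, 1, function(b)
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = ""))
  n_studies <- rowSums(!is.na(B))
  n_tot <- rowSums(Nmat)
  if (scheme == "stderr") {
    W <- 1 / SE^2
    W[is.na(B)] <- NA
    sw <- rowSums(W, na.rm = TRUE)
    b_meta <- rowSums(W * B, na.rm = TRUE) / sw
    se_meta <- 1 / sqrt(sw)
    z <- b_meta / se_meta
  } else {
    Z <- B / SE
    wz <- sqrt(Nmat)
    wz[is.na(B)] <- NA
    z <- rowSums(wz * Z, na.rm = TRUE) / sqrt(rowSums(wz^2, na.rm = TRUE))
    b_meta <- NA_real_
    se_meta <- NA_real_
  }
  out <- data.frame(
    id = paste0(ref_tab$chrom, ":", ref_tab$pos),
    chrom = ref_tab$chrom, pos = ref_tab$pos,
    ref = ref_tab$ref, alt = ref_tab$alt,
    b_meta = b_meta, se_meta = se_meta, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    neglog10p = -(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) +
                  log(2)) / log(10),
    n_studies = n_studies, n = n_tot, direction = direction)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}
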