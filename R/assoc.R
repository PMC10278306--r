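#' Mixed-linear-model association scan on allele dosages
#'
#' Per-variant association of ALT-allele dosage with a phenotype under the
#' model \eqn{y = 1\mu + x b + g_A + e}, where the random polygenic term
#' \eqn{g_A \sim N(0, G_A \sigma^2_A)} controls for population structure and
#' relatedness. The variance components are estimated once under the
#' no-marker null by single-component REML; the GRM is eigendecomposed once;
#' and each variant's effect \code{b} and standard error are obtained by
#' generalized least squares in the rotated space with the covariance fixed
#' at the null estimates (the EMMAX-style approximation). Two-sided P-values
#' use the standard normal on \code{b/se}, appropriate for cohorts of
#' hundreds to thousands of animals.
#'
#' For X-chromosome scans the polygenic GRM must be built from autosomal
#' SNPs only (leave-one-chromosome-out by construction); the function
#' errors if any scanned variant is part of the GRM SNP set, unless
#' \code{allow_grm_overlap = TRUE} (for generic non-LOCO autosomal scans).
#'
#' @param dm a \code{\link{dosage_matrix}} of the variants to test (already
#'   sequence-filtered).
#' @param y phenotype vector aligned to \code{dm} samples, or a long-format
#'   phenotype data.frame (then \code{trait} selects the trait and samples
#'   are intersected by id).
#' @param G_A \code{grm_matrix} for polygenic control (autosomal SNPs).
#' @param trait trait name (annotation; required when \code{y} is a
#'   data.frame).
#' @param population population label stored in the result.
#' @param allow_grm_overlap allow tested variants inside the GRM SNP set.
#' @return object of class \code{scan_result}: list with \code{trait},
#'   \code{population}, \code{stats} (data.frame sorted by chrom, pos with
#'   columns \code{id, chrom, pos, effect_allele, freq, b, se, p,
#'   neglog10p, n}) and \code{vc} (null-model variance components).
#' @export
run_scan <- function(dm, y, G_A, trait = "trait", population = "pop",
                     allow_grm_overlap = FALSE) {
  stopifnot(inherits(dm, "dosage_matrix"), inherits(G_A, "grm_matrix"))
  if (is.data.frame(y)) {
    y <- phenotype_vector(y, trait, dm$samples$sample_id)
  }
  if (!identical(dm$samples$sample_id, G_A$samples)) {
    stop("dosage matrix and GRM cover different samples/orders")
  }
  keep <- !is.na(y)
  if (!all(keep)) {
    message("run_scan: dropping ", sum(!keep), " samples without phenotype; ",
            sum(keep), " analyzed")
    dm <- dm[which(keep), ]
    idx <- which(keep)
    G_A <- structure(list(values = G_A$values[idx, idx],
                          samples = G_A$samples[idx], n_snps = G_A$n_snps,
                          snp_ids = G_A$snp_ids,
                          snp_set_label = G_A$snp_set_label),
                     class = "grm_matrix")
    y <- y[idx]
  }
  if (!allow_grm_overlap && !is.null(G_A$snp_ids)) {
    ov <- intersect(dm$variants$id, G_A$snp_ids)
    if (length(ov)) {
      stop("scanned variant(s) present in the polygenic GRM SNP set ",
           "(leave-one-chromosome-out violated): ",
           paste(utils::head(ov, 5), collapse = ", "))
    }
  }
  n <- length(y)
  null_fit <- fit_reml_single(y, G_A)
  U <- null_fit$eigen$vectors
  lam <- pmax(null_fit$eigen$values, 0)
  if (null_fit$sigma2_g > 0) {
    d <- null_fit$sigma2_g * lam + null_fit$sigma2_e
  } else {
    d <- rep(null_fit$sigma2_e, n)
  }
  w <- 1 / d
  yt <- as.vector(crossprod(U, y))
  ot <- as.vector(crossprod(U, rep(1, n)))
  Xt <- crossprod(U, dm$dosages)            # n x m rotated dosages

  sdx <- apply(dm$dosages, 2, stats::sd)
  degenerate <- sdx == 0
  if (any(degenerate)) {
    warning("skipping ", sum(degenerate),
            " variant(s) with zero dosage variance")
  }
  a11 <- sum(ot^2 * w)
  a12 <- as.vector(crossprod(Xt, ot * w))
  a22 <- as.vector(crossprod(Xt^2, w))
  b1 <- sum(ot * yt * w)
  b2 <- as.vector(crossprod(Xt, yt * w))
  det <- a11 * a22 - a12^2
  det[degenerate] <- NA_real_
  b <- (a11 * b2 - a12 * b1) / det
  se <- suppressWarnings(sqrt(a11 / det))

  v <- dm$variants
  z <- b / se
  stats_df <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                         effect_allele = v$alt,
                         freq = colMeans(dm$dosages) / 2,
                         b = b, se = se,
                         p = 2 * stats::pnorm(-abs(z)),
                         neglog10p = -(stats::pnorm(abs(z),
                                                    lower.tail = FALSE,
                                                    log.p = TRUE) +
                                       log(2)) / log(10),
                         n = n)
  stats_df <- stats_df[!degenerate, ]
  stats_df <- stats_df[order(stats_df$chrom, stats_df$pos, stats_df$id), ]
  rownames(stats_df) <- NULL
  structure(list(trait = trait, population = population, stats = stats_df,
                 vc = c(sigma2_a = null_fit$sigma2_g,
                        sigma2_e = null_fit$sigma2_e)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", x$trait, "in", x$population, "-", nrow(x$stats),
      "variants, n =", x$stats$n[1], "\n")
  top <- x$stats[which.max(x$stats$neglog10p), ]
  cat(sprintf("  top: %s (%s:%d) -log10(p) = %.2f\n", top$id, top$chrom,
              top$pos, top$neglog10p))
  invisible(x)
}

#' Genomic inflation factor
#'
#' Median-based lambda of a set of two-sided P-values:
#' \code{median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1, lower = FALSE)}.
#'
#' @param p vector of P-values.
#' @return the inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write scan summary statistics as TSV
#'
#' Columns \code{chr, snp, bp, a1, a2, freq, b, se, p, n}
#' (information-compatible with GCTA .mlma output; \code{a1} is the tested
#' ALT allele).
#'
#' @param scan a \code{scan_result}.
#' @param dm the \code{dosage_matrix} the scan was run on (for allele
#'   metadata).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scan <- function(scan, dm, path) {
  v <- dm$variants[match(scan$stats$id, dm$variants$id), ]
  out <- data.frame(chr = scan$stats$chrom, snp = scan$stats$id,
                    bp = scan$stats$pos, a1 = v$alt, a2 = v$ref,
                    freq = scan$stats$freq, b = scan$stats$b,
                    se = scan$stats$se, p = scan$stats$p, n = scan$stats$n)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
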