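#' Genome-wide significance threshold on the -log10 scale
#'
#' Bonferroni-corrected threshold \code{-log10(alpha / n_tests)}. With
#' \code{alpha = 0.05} and one million independent tests this gives the
#' conventional 7.3.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of independent tests (>= 1).
#' @return the \code{-log10(P)} significance threshold.
#' @export
significance_threshold <- function(alpha = 0.05, n_tests = 1e6) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (n_tests < 1) stop("n_tests must be >= 1")
  -log10(alpha / n_tests)
}

#' Conditional Wald statistic for LD peeling
#'
#' Tests whether variant i's signal is explained by the lead variant through
#' linkage disequilibrium:
#' \deqn{T_{NEW} = \frac{b_i - b_{LEAD} \, r_{i,LEAD}}{SE_i}}
#' where \code{r} is the signed Pearson correlation of allele dosages
#' between the two variants. \code{T_i = b_i / SE_i} is the marginal Wald
#' statistic; \code{p_new} is the two-sided normal tail of \code{T_new}.
#'
#' @param b_i,se_i effect and standard error of variant i (\code{se_i > 0}).
#' @param b_lead effect of the lead variant.
#' @param r_i_lead signed dosage correlation between i and the lead, in
#'   [-1, 1].
#' @return list with \code{T_new}, \code{p_new}, \code{T_i} (vectorized over
#'   variant i).
#' @export
conditional_statistic <- function(b_i, se_i, b_lead, r_i_lead) {
  if (any(se_i <= 0)) stop("se_i must be positive")
  if (any(abs(r_i_lead) > 1 + 1e-12)) stop("r must lie in [-1, 1]")
  T_new <- (b_i - b_lead * r_i_lead) / se_i
  list(T_new = T_new,
       p_new = 2 * stats::pnorm(-abs(T_new)),
       T_i = b_i / se_i)
}

#' Peeling configuration
#'
#' @param sig_threshold_neglog10p \code{-log10(P)} significance threshold
#'   (default 7.3, i.e. 0.05 Bonferroni-corrected for ~1 million tests).
#' @param window_halfwidth_bp half-width of the window centered on the lead
#'   variant (default 10 Mb, i.e. a 20-Mb window).
#' @param ci_ld_threshold minimum \code{|r|} with the lead for membership in
#'   the QTL confidence interval (default 0.7).
#' @return list of class \code{peeling_config}.
#' @export
peeling_config <- function(sig_threshold_neglog10p = 7.3,
                           window_halfwidth_bp = 10000000L,
                           ci_ld_threshold = 0.7) {
  if (sig_threshold_neglog10p <= 0) stop("threshold must be positive")
  if (window_halfwidth_bp <= 0) stop("window halfwidth must be positive")
  if (ci_ld_threshold <= 0 || ci_ld_threshold > 1) {
    stop("ci_ld_threshold must lie in (0, 1]")
  }
  structure(list(sig_threshold_neglog10p = sig_threshold_neglog10p,
                 window_halfwidth_bp = as.numeric(window_halfwidth_bp),
                 ci_ld_threshold = ci_ld_threshold),
            class = "peeling_config")
}

#' Iterative LD-based QTL calling
#'
#' Turns a single-chromosome association scan (within-population or
#' meta-analysis) plus a dosage reference into an ordered list of QTL
#' regions with LD-defined confidence intervals, by iterating:
#' \enumerate{
#'   \item take as lead the variant with the maximal \code{-log10(P)} at or
#'     above the threshold (ties: smallest position, then id);
#'   \item select all working-set variants within the window centered on the
#'     lead;
#'   \item compute the signed dosage correlation \code{r} between the lead
#'     and each window variant in the reference cohort;
#'   \item the confidence interval is the set of window variants with
#'     \code{|r|} at or above the LD threshold (the lead included, r = 1);
#'   \item for window variants outside the interval, compute the conditional
#'     statistic \code{T_new}; those no longer significant
#'     (\code{-log10(p_new)} below the threshold) whose \code{T_new} keeps
#'     the sign of the marginal \code{T_i} are explained by the lead;
#'   \item remove interval members and explained variants from the working
#'     set and repeat until no variant reaches the threshold.
#' }
#' Variants outside the window are never touched within an iteration. The
#' interval bounds are the min/max positions of its member variants.
#'
#' @param scan a \code{scan_result}, \code{meta_result}, or data.frame with
#'   columns \code{id, chrom, pos, b, se, p, neglog10p} (meta results use
#'   \code{b_meta}/\code{se_meta}).
#' @param dm \code{\link{dosage_matrix}} supplying dosages for LD; must
#'   contain every scanned variant.
#' @param cfg a \code{\link{peeling_config}}.
#' @param trait,analysis labels stored on the output rows.
#' @param trace optional path of a text log auditing every removal.
#' @return data.frame of class \code{qtl_regions}, one row per QTL in
#'   discovery order: \code{trait, analysis, lead_id, lead_chrom, lead_bp,
#'   lead_neglog10p, lead_b, lead_se, ci_start_bp, ci_end_bp,
#'   ci_length_bp, n_ci_variants, iteration_index}, with the member ids in
#'   \code{attr(, "ci_variant_ids")} (a list named by \code{lead_id}).
#' @export
call_qtl <- function(scan, dm, cfg = peeling_config(), trait = NULL,
                     analysis = NULL, trace = NULL) {
  stopifnot(inherits(dm, "dosage_matrix"), inherits(cfg, "peeling_config"))
  if (inherits(scan, "scan_result")) {
    if (is.null(trait)) trait <- scan$trait
    if (is.null(analysis)) analysis <- scan$population
    tab <- scan$stats
  } else {
    tab <- as.data.frame(scan)
    if ("b_meta" %in% names(tab)) {
      tab$b <- tab$b_meta
      tab$se <- tab$se_meta
      if (is.null(analysis)) analysis <- "meta"
    }
  }
  if (is.null(trait)) trait <- "trait"
  if (is.null(analysis)) analysis <- "analysis"
  if (length(unique(tab$chrom)) > 1) {
    stop("call_qtl works on a single chromosome; got: ",
         paste(unique(tab$chrom), collapse = ", "))
  }
  missing_ids <- setdiff(tab$id, dm$variants$id)
  if (length(missing_ids)) {
    stop("scan variants missing from the LD reference: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ..." else "")
  }
  thr <- cfg$sig_threshold_neglog10p
  H <- cfg$window_halfwidth_bp
  ld_thr <- cfg$ci_ld_threshold
  X <- dm$dosages[, tab$id, drop = FALSE]
  tracef <- if (!is.null(trace)) file(trace, open = "wt") else NULL
  on.exit(if (!is.null(tracef)) close(tracef))

  work <- seq_len(nrow(tab))
  regions <- list()
  ci_ids <- list()
  iter <- 0L
  while (length(work)) {
    cand <- work[tab$neglog10p[work] >= thr]
    if (!length(cand)) break
    iter <- iter + 1L
    # lead: max neglog10p; ties by smallest bp then id
    o <- order(-tab$neglog10p[cand], tab$pos[cand], tab$id[cand])
    lead <- cand[o[1]]
    in_win <- work[abs(tab$pos[work] - tab$pos[lead]) <= H]
    r <- suppressWarnings(
      as.vector(stats::cor(X[, tab$id[lead]], X[, tab$id[in_win],
                                                drop = FALSE])))
    r[is.na(r)] <- 0
    r[in_win == lead] <- 1
    ci <- in_win[abs(r) >= ld_thr]
    outside <- setdiff(in_win, ci)
    explained <- integer(0)
    if (length(outside)) {
      ro <- r[match(outside, in_win)]
      cs <- conditional_statistic(tab$b[outside], tab$se[outside],
                                  tab$b[lead], ro)
      expl <- -log10(cs$p_new) < thr & sign(cs$T_new) == sign(cs$T_i)
      explained <- outside[expl]
      if (!is.null(tracef) && any(expl)) {
        writeLines(sprintf(
          "iter %d lead %s explained %s r=%.4f T_new=%.4f p_new=%.3g",
          iter, tab$id[lead], tab$id[explained], ro[expl],
          cs$T_new[expl], cs$p_new[expl]), tracef)
      }
    }
    if (!is.null(tracef)) {
      writeLines(sprintf("iter %d lead %s ci_n %d removed %d", iter,
                         tab$id[lead], length(ci), length(explained)),
                 tracef)
    }
    regions[[iter]] <- data.frame(
      trait = trait, analysis = analysis,
      lead_id = tab$id[lead], lead_chrom = tab$chrom[lead],
      lead_bp = tab$pos[lead], lead_neglog10p = tab$neglog10p[lead],
      lead_b = tab$b[lead], lead_se = tab$se[lead],
      ci_start_bp = min(tab$pos[ci]), ci_end_bp = max(tab$pos[ci]),
      ci_length_bp = max(tab$pos[ci]) - min(tab$pos[ci]),
      n_ci_variants = length(ci), iteration_index = iter)
    ci_ids[[tab$id[lead]]] <- tab$id[ci]
    work <- setdiff(work, c(ci, explained))
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(trait = character(), analysis = character(),
               lead_id = character(), lead_chrom = character(),
               lead_bp = numeric(), lead_neglog10p = numeric(),
               lead_b = numeric(), lead_se = numeric(),
               ci_start_bp = numeric(), ci_end_bp = numeric(),
               ci_length_bp = numeric(), n_ci_variants = integer(),
               iteration_index = integer())
  rownames(out) <- NULL
  attr(out, "ci_variant_ids") <- ci_ids
  class(out) <- c("qtl_regions", "data.frame")
  out
}

#' Write QTL regions as TSV
#'
#' Columns: trait, analysis, lead_snp, lead_chr, lead_bp, lead_neglog10p,
#' ci_start, ci_end, ci_n_variants, ci_kbp, iteration.
#'
#' @param qtl a \code{qtl_regions} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qtl <- function(qtl, path) {
  out <- data.frame(trait = qtl$trait, analysis = qtl$analysis,
                    lead_snp = qtl$lead_id, lead_chr = qtl$lead_chrom,
                    lead_bp = qtl$lead_bp,
                    lead_neglog10p = qtl$lead_neglog10p,
                    ci_start = qtl$ci_start_bp, ci_end = qtl$ci_end_bp,
                    ci_n_variants = qtl$n_ci_variants,
                    ci_kbp = qtl$ci_length_bp / 1000,
                    iteration = qtl$iteration_index)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
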