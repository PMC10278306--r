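#' Pipeline configuration
#'
#' Bundles the stage configurations of the full analysis: simulate (or load)
#' a cohort, per-population variant QC, GRM construction, two-component REML
#' heritability partition, X-chromosome mixed-model scans, fixed-effects
#' meta-analysis, and QTL peeling.
#'
#' @param sim a \code{\link{sim_config}} describing the cohort to simulate,
#'   or \code{NULL} with \code{dosages_path}/\code{pheno_path} set.
#' @param dosages_path,pheno_path input files used when \code{sim} is
#'   \code{NULL} (dosage TSV dialect and long-format phenotype TSV); the
#'   sample metadata must then carry a \code{population} column upstream or
#'   all samples are treated as one population.
#' @param qc a \code{\link{qc_thresholds}}.
#' @param peeling a \code{\link{peeling_config}}.
#' @param out_dir output directory (created if missing).
#' @param seed integer; the only entropy source of the pipeline. The
#'   simulation consumes it directly; every later stage is deterministic
#'   given its inputs.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), dosages_path = NULL,
                            pheno_path = NULL, qc = qc_thresholds(),
                            peeling = peeling_config(),
                            out_dir = tempfile("xqtl_run_"), seed = 1L) {
  if (is.null(sim) && (is.null(dosages_path) || is.null(pheno_path))) {
    stop("either a sim_config or dosage + phenotype paths are required")
  }
  if (!is.null(dosages_path) && !file.exists(dosages_path)) {
    stop("dosage file not found: ", dosages_path)
  }
  if (!is.null(pheno_path) && !file.exists(pheno_path)) {
    stop("phenotype file not found: ", pheno_path)
  }
  structure(list(sim = sim, dosages_path = dosages_path,
                 pheno_path = pheno_path, qc = qc, peeling = peeling,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: \code{sim} (fields of
#' \code{\link{sim_config}}; \code{planted_qtl} as a list of
#' \code{{chrom, pos, effect}} maps), \code{dosages}, \code{pheno},
#' \code{qc} (fields of \code{\link{qc_thresholds}}), \code{peeling}
#' (fields of \code{\link{peeling_config}}), \code{out_dir}, \code{seed}.
#'
#' @param path YAML file path.
#' @return a \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  yml <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(yml$sim)) {
    args <- yml$sim
    if (!is.null(args$planted_qtl)) {
      args$planted_qtl <- do.call(rbind, lapply(args$planted_qtl,
                                                as.data.frame))
      args$planted_qtl$chrom <- as.character(args$planted_qtl$chrom)
    }
    sim <- do.call(sim_config, args)
  }
  pipeline_config(
    sim = sim, dosages_path = yml$dosages, pheno_path = yml$pheno,
    qc = do.call(qc_thresholds, if (is.null(yml$qc)) list() else yml$qc),
    peeling = do.call(peeling_config,
                      if (is.null(yml$peeling)) list() else yml$peeling),
    out_dir = if (is.null(yml$out_dir)) tempfile("xqtl_run_") else
      yml$out_dir,
    seed = if (is.null(yml$seed)) 1L else yml$seed)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full X-chromosome analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-population sequence QC -> GRMs ->
#' two-component REML -> X-chromosome mixed-model scan -> fixed-effects
#' meta-analysis -> QTL peeling, writing all stage outputs plus a
#' QTL-count matrix (populations + meta x trait), a QTL summary table
#' (mean/min/max of lead significance, interval variant counts and kbp),
#' and a \code{manifest.json} under \code{cfg$out_dir}.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly: list with \code{files} (named paths),
#'   \code{counts} (per-stage row counts), \code{qtl_count_matrix} and
#'   \code{qtl_summary}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  counts <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(cfg$sim)) {
    simcfg <- cfg$sim
    simcfg$seed <- cfg$seed
    sim <- run_stage("simulate", simulate_population(simcfg))
    dm <- sim$dm
    pheno <- sim$pheno
    files$truth <- file.path(cfg$out_dir, "truth.json")
    jsonlite::write_json(sim$truth, files$truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    stage_log("simulate", nrow(dm$dosages), " samples, ",
              ncol(dm$dosages), " variants")
  } else {
    dm <- run_stage("load", read_dosages(cfg$dosages_path, "tsv"))
    pheno <- run_stage("load", read_phenotypes(cfg$pheno_path))
    stage_log("load", nrow(dm$dosages), " samples, ", ncol(dm$dosages),
              " variants")
  }
  trait <- unique(pheno$trait)[1]
  pops <- if (is.null(dm$samples$population)) "ALL" else
    unique(dm$samples$population)

  scans <- list()
  dms_x <- list()
  vc_list <- list()
  qtl_tabs <- list()
  for (pop in pops) {
    rows <- if (identical(pops, "ALL")) seq_len(nrow(dm$dosages)) else
      which(dm$samples$population == pop)
    dmp <- dm[rows, ]
    qcres <- run_stage("qc", apply_variant_qc(dmp, cfg$qc,
                                              "sequence_filter"))
    dmp <- qcres$dm
    stage_log("qc", pop, ": ", ncol(dmp$dosages), " variants kept (",
              paste(qcres$report$removed, collapse = "/"),
              " removed by ", paste(qcres$report$criterion, collapse = "/"),
              ")")
    counts[[paste0("variants_", pop)]] <- ncol(dmp$dosages)
    is_x <- dmp$variants$chrom == "X"
    G_A <- run_stage("grm", compute_grm(dmp, which(!is_x), "autosomal"))
    G_X <- run_stage("grm", compute_grm(dmp, which(is_x), "X"))
    y <- phenotype_vector(pheno, trait, dmp$samples$sample_id)
    vc <- run_stage("reml", fit_reml_two_components(unname(y), G_A, G_X))
    h2 <- heritability_from_components(vc)
    vc_list[[pop]] <- c(list(population = pop, trait = trait),
                        vc[c("sigma2_a", "sigma2_x", "sigma2_e",
                             "se_sigma2_a", "se_sigma2_x", "se_sigma2_e",
                             "loglik", "n_iter", "converged")],
                        h2[c("h2", "h2_aut", "h2_x", "se_h2_aut",
                             "se_h2_x")])
    f <- file.path(cfg$out_dir, sprintf("vc_%s_%s.json", trait, pop))
    jsonlite::write_json(vc_list[[pop]], f, auto_unbox = TRUE, digits = NA)
    files[[paste0("vc_", pop)]] <- f
    stage_log("reml", pop, sprintf(": h2_aut %.3f h2_x %.3f", h2$h2_aut,
                                   h2$h2_x))

    dmx <- dmp[, which(is_x)]
    scan <- run_stage("scan", run_scan(dmx, unname(y), G_A, trait = trait,
                                       population = pop))
    scans[[pop]] <- scan
    dms_x[[pop]] <- dmx
    f <- file.path(cfg$out_dir, sprintf("scan_%s_%s.tsv", trait, pop))
    write_scan(scan, dmx, f)
    files[[paste0("scan_", pop)]] <- f
    counts[[paste0("scan_", pop)]] <- nrow(scan$stats)
    stage_log("scan", pop, ": ", nrow(scan$stats), " X variants tested")

    qtl <- run_stage("qtl", call_qtl(scan, dmx, cfg$peeling, trait = trait,
                                     analysis = pop))
    qtl_tabs[[pop]] <- qtl
    f <- file.path(cfg$out_dir, sprintf("qtl_%s_%s.tsv", trait, pop))
    write_qtl(qtl, f)
    files[[paste0("qtl_", pop)]] <- f
    stage_log("qtl", pop, ": ", nrow(qtl), " QTL")
  }

  meta <- run_stage("meta", fixed_effects_meta(scans, dms_x))
  f <- file.path(cfg$out_dir, sprintf("meta_%s.tsv", trait))
  data.table::fwrite(meta, f, sep = "\t")
  files$meta <- f
  counts$meta <- nrow(meta)
  stage_log("meta", nrow(meta), " variants combined across ",
            length(scans), " populations")

  # LD reference for the meta QTL call: all populations, X variants only
  dm_x_all <- dm[, which(dm$variants$chrom == "X")]
  midx <- match(paste0(meta$chrom, ":", meta$pos),
                paste0(dm_x_all$variants$chrom, ":", dm_x_all$variants$pos))
  vref <- dm_x_all$variants[midx, ]
  vref$id <- meta$id  # align id convention with the meta table
  vref$maf <- NULL
  meta_ref <- dosage_matrix(dm_x_all$dosages[, midx, drop = FALSE], vref,
                            dm_x_all$samples)
  qtl_meta <- run_stage("qtl", call_qtl(meta, meta_ref, cfg$peeling,
                                        trait = trait, analysis = "meta"))
  qtl_tabs$meta <- qtl_meta
  f <- file.path(cfg$out_dir, sprintf("qtl_%s_meta.tsv", trait))
  write_qtl(qtl_meta, f)
  files$qtl_meta <- f
  stage_log("qtl", "meta: ", nrow(qtl_meta), " QTL")

  analyses <- names(qtl_tabs)
  count_mat <- matrix(vapply(qtl_tabs, nrow, integer(1)), ncol = 1,
                      dimnames = list(analyses, trait))
  all_qtl <- do.call(rbind, qtl_tabs)
  qtl_summary <- do.call(rbind, lapply(analyses, function(a) {
    q <- qtl_tabs[[a]]
    if (!nrow(q)) {
      return(data.frame(analysis = a, n_qtl = 0L,
                        neglog10p_mean = NA, neglog10p_min = NA,
                        neglog10p_max = NA, ci_n_variants_mean = NA,
                        ci_kbp_mean = NA))
    }
    data.frame(analysis = a, n_qtl = nrow(q),
               neglog10p_mean = mean(q$lead_neglog10p),
               neglog10p_min = min(q$lead_neglog10p),
               neglog10p_max = max(q$lead_neglog10p),
               ci_n_variants_mean = mean(q$n_ci_variants),
               ci_kbp_mean = mean(q$ci_length_bp) / 1000)
  }))
  f <- file.path(cfg$out_dir, "qtl_summary.tsv")
  data.table::fwrite(qtl_summary, f, sep = "\t")
  files$qtl_summary <- f
  counts$qtl_total <- if (is.null(all_qtl)) 0L else nrow(all_qtl)

  manifest <- list(files = lapply(files, normalizePath),
                   counts = counts,
                   qtl_count_matrix = as.data.frame(count_mat),
                   qtl_summary = qtl_summary,
                   seed = cfg$seed, trait = trait)
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  manifest$files$manifest <- normalizePath(mf)
  stage_log("done", "outputs in ", cfg$out_dir)
  invisible(manifest)
}
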