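#' Simulation configuration
#'
#' Parameters of the founder-mosaic cohort simulator. The simulated design
#' mirrors a multi-population, all-female dairy cohort: each population has
#' its own founder haplotype pool, daughters receive a recombined maternal
#' haplotype on every chromosome, and on the X chromosome the paternal copy
#' is transmitted intact from the sire's single X (no recombination in
#' males). Half-sib families sharing whole paternal X haplotypes give the X
#' elevated linkage disequilibrium relative to the autosome, as observed in
#' cattle.
#'
#' @param n_populations number of populations (breeds).
#' @param n_females_per_pop phenotyped, genotyped females per population.
#' @param n_founder_haplotypes founder haplotypes per population pool; a
#'   small pool produces strong within-population LD.
#' @param n_autosomal_variants variants simulated on the autosome
#'   (chromosome label \code{"2"}).
#' @param n_x_variants variants simulated on the X (label \code{"X"}).
#' @param chrom_length_bp simulated length of each chromosome in bp
#'   (default 133.3 Mb, the non-pseudoautosomal X of the bovine assembly).
#' @param target_h2_aut expected fraction of phenotypic variance from
#'   autosomal polygenic effects.
#' @param target_h2_x expected fraction from X-linked effects;
#'   \code{target_h2_aut + target_h2_x} must be < 1.
#' @param planted_qtl data.frame with columns \code{chrom}, \code{pos},
#'   \code{effect} (one row per major QTL), or \code{NULL}. Effects are in
#'   phenotype standard deviations per standard deviation of allele dosage,
#'   so the expected association z-statistic is about
#'   \code{effect * sqrt(n)}. A variant is placed at each planted position.
#' @param recomb_rate_female per-bp switch probability of the female
#'   recombination/mosaic process (default 2e-7, giving LD decay over a few
#'   Mb, comparable to within-breed cattle LD at 50k density).
#' @param n_sires_per_pop number of transmitting sires per population;
#'   daughters are assigned to sires at random. Fewer sires means stronger
#'   sharing of intact paternal X haplotypes.
#' @param trait_name name used in the emitted phenotype table.
#' @param seed integer seed driving all randomness of one simulation.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_populations = 3, n_females_per_pop = 1000,
                       n_founder_haplotypes = 40,
                       n_autosomal_variants = 800, n_x_variants = 400,
                       chrom_length_bp = 133300000,
                       target_h2_aut = 0.30, target_h2_x = 0.02,
                       planted_qtl = NULL,
                       recomb_rate_female = 2e-7,
                       n_sires_per_pop = 25,
                       trait_name = "YD", seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              n_females_per_pop = as.integer(n_females_per_pop),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              n_autosomal_variants = as.integer(n_autosomal_variants),
              n_x_variants = as.integer(n_x_variants),
              chrom_length_bp = as.numeric(chrom_length_bp),
              target_h2_aut = target_h2_aut, target_h2_x = target_h2_x,
              planted_qtl = planted_qtl,
              recomb_rate_female = recomb_rate_female,
              n_sires_per_pop = as.integer(n_sires_per_pop),
              trait_name = trait_name, seed = as.integer(seed))
  counts <- c(cfg$n_populations, cfg$n_females_per_pop,
              cfg$n_founder_haplotypes, cfg$n_autosomal_variants,
              cfg$n_x_variants, cfg$n_sires_per_pop)
  if (any(counts <= 0)) stop("all simulation counts must be positive")
  if (cfg$target_h2_aut < 0 || cfg$target_h2_x < 0 ||
      cfg$target_h2_aut + cfg$target_h2_x >= 1) {
    stop("infeasible variance targets: target_h2_aut + target_h2_x must be < 1")
  }
  if (!is.null(planted_qtl)) {
    need <- c("chrom", "pos", "effect")
    if (!all(need %in% names(planted_qtl))) {
      stop("planted_qtl needs columns chrom, pos, effect")
    }
    if (!all(planted_qtl$chrom %in% c("2", "X"))) {
      stop("planted_qtl chrom must be \"2\" (autosome) or \"X\"")
    }
    if (any(planted_qtl$pos < 1 | planted_qtl$pos > chrom_length_bp)) {
      stop("planted_qtl position outside simulated chromosome")
    }
    if (any(planted_qtl$chrom == "X") && target_h2_x + target_h2_aut +
        0 >= 1) stop("infeasible targets")
  }
  structure(cfg, class = "sim_config")
}

# One founder-mosaic haplotype: copy segments from a pool of haplotypes,
# switching donors between adjacent variants with probability
# 1 - exp(-rate * gap_bp).
mosaic_haplotype <- function(pool, pos, rate) {
  m <- length(pos)
  if (rate <= 0) {
    return(pool[sample.int(nrow(pool), 1L), ])
  }
  switch_p <- 1 - exp(-rate * diff(pos))
  switches <- stats::runif(m - 1) < switch_p
  seg <- c(1L, 1L + cumsum(switches))
  donors <- sample.int(nrow(pool), seg[m], replace = TRUE)
  pool[cbind(donors[seg], seq_len(m))]
}

#' Simulate a multi-population all-female cohort
#'
#' Generates LD-structured autosomal and X-linked allele dosages, a
#' polygenic phenotype with a planted autosomal/X variance split, and the
#' simulation truth. Each population gets an independent founder pool drawn
#' around shared ancestral allele frequencies, so variants segregate in all
#' populations at (somewhat) different frequencies, as across cattle breeds.
#'
#' Transmission rules: the maternal haplotype of every chromosome is a fresh
#' founder mosaic with the female per-bp switch rate; the paternal autosome
#' is a recombined mosaic of the sire's two haplotypes; the paternal X is
#' the sire's single X copied intact (males do not recombine on X).
#'
#' Phenotypes are built on standardized dosages: each variant receives a
#' Gaussian effect scaled so the expected phenotypic variance fractions
#' equal \code{target_h2_aut} and \code{target_h2_x}; planted major QTL are
#' added on top and counted inside the corresponding genetic component;
#' residuals are Gaussian with variance topping the total up to 1.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{dm} (a \code{\link{dosage_matrix}}
#'   covering all populations, with \code{population}, \code{sex} and
#'   \code{sire} sample columns), \code{pheno} (long-format phenotype
#'   data.frame) and \code{truth} (list: per-variant standardized effects
#'   per population, realized variance components per population, the
#'   planted QTL table, and the targets).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  L <- cfg$chrom_length_bp
  pos_a <- sort(sample.int(L, cfg$n_autosomal_variants))
  pos_x <- sort(sample.int(L, cfg$n_x_variants))
  # Force a simulated variant at every planted position.
  pq <- cfg$planted_qtl
  if (!is.null(pq)) {
    for (k in seq_len(nrow(pq))) {
      if (pq$chrom[k] == "2") {
        pos_a[which.min(abs(pos_a - pq$pos[k]))] <- pq$pos[k]
      } else {
        pos_x[which.min(abs(pos_x - pq$pos[k]))] <- pq$pos[k]
      }
    }
    pos_a <- sort(pos_a); pos_x <- sort(pos_x)
  }
  chrom <- c(rep("2", length(pos_a)), rep("X", length(pos_x)))
  pos <- c(pos_a, pos_x)
  m <- length(pos)
  is_x <- chrom == "X"
  p_anc <- stats::runif(m, 0.1, 0.9)
  variants <- data.frame(
    id = paste0(chrom, ":", pos), chrom = chrom, pos = pos,
    ref = "A", alt = "B", imputation_r2 = round(stats::runif(m, 0.5, 1), 3))

  pops <- paste0("POP", seq_len(cfg$n_populations))
  n <- cfg$n_females_per_pop
  K <- cfg$n_founder_haplotypes
  S <- cfg$n_sires_per_pop
  rate <- cfg$recomb_rate_female

  all_dos <- vector("list", cfg$n_populations)
  all_samp <- vector("list", cfg$n_populations)
  all_y <- vector("list", cfg$n_populations)
  eff_list <- vector("list", cfg$n_populations)
  comp_list <- vector("list", cfg$n_populations)

  # The X has a smaller effective population size than the autosomes
  # (3 X copies per 4 autosomal copies), realized here as a reduced X
  # founder pool; together with intact paternal transmission this elevates
  # X-linked LD.
  K_x <- max(2L, as.integer(ceiling(0.75 * K)))

  for (ip in seq_along(pops)) {
    founders <- matrix(stats::rbinom(K * m, 1L, rep(p_anc, each = K)),
                       nrow = K, ncol = m)
    founders[(K_x + 1):K, is_x] <- NA_integer_
    # condition every founder pool column on segregation (variants are
    # ascertained as polymorphic, as on a genotyping chip)
    for (j in seq_len(m)) {
      pool <- if (is_x[j]) K_x else K
      cs <- sum(founders[seq_len(pool), j])
      if (cs == 0L) founders[sample.int(pool, 1L), j] <- 1L
      if (cs == pool) founders[sample.int(pool, 1L), j] <- 0L
    }
    # sires: two autosomal haplotypes and one X haplotype each
    sire_a1 <- t(vapply(seq_len(S), function(i)
      mosaic_haplotype(founders[, !is_x, drop = FALSE], pos_a, rate),
      numeric(sum(!is_x))))
    sire_a2 <- t(vapply(seq_len(S), function(i)
      mosaic_haplotype(founders[, !is_x, drop = FALSE], pos_a, rate),
      numeric(sum(!is_x))))
    founders_x <- founders[seq_len(K_x), is_x, drop = FALSE]
    sire_x <- t(vapply(seq_len(S), function(i)
      mosaic_haplotype(founders_x, pos_x, rate),
      numeric(sum(is_x))))
    sire_of <- sample.int(S, n, replace = TRUE)
    dos <- matrix(0, n, m)
    for (i in seq_len(n)) {
      mat_a <- mosaic_haplotype(founders[, !is_x, drop = FALSE], pos_a, rate)
      mat_x <- mosaic_haplotype(founders_x, pos_x, rate)
      s <- sire_of[i]
      pat_a <- mosaic_haplotype(rbind(sire_a1[s, ], sire_a2[s, ]), pos_a, rate)
      pat_x <- sire_x[s, ]  # intact: no male recombination on X
      dos[i, !is_x] <- mat_a + pat_a
      dos[i, is_x] <- mat_x + pat_x
    }
    # standardized dosages (monomorphic columns contribute no variance)
    sds <- apply(dos, 2, stats::sd)
    Z <- sweep(dos, 2, colMeans(dos), "-")
    ok <- sds > 0
    Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sds[ok], "/")
    Z[, !ok] <- 0

    eff <- numeric(m)
    if (cfg$target_h2_aut > 0) {
      ma <- sum(!is_x)
      eff[!is_x] <- stats::rnorm(ma) * sqrt(cfg$target_h2_aut / ma)
    }
    if (cfg$target_h2_x > 0) {
      mx <- sum(is_x)
      eff[is_x] <- stats::rnorm(mx) * sqrt(cfg$target_h2_x / mx)
    }
    if (!is.null(pq)) {
      idx <- match(paste0(pq$chrom, ":", pq$pos), variants$id)
      if (anyNA(idx)) stop("planted QTL position missing among variants")
      eff[idx] <- eff[idx] + pq$effect
    }
    g_a <- as.vector(Z[, !is_x, drop = FALSE] %*% eff[!is_x])
    g_x <- as.vector(Z[, is_x, drop = FALSE] %*% eff[is_x])
    sig_e <- sqrt(max(0, 1 - cfg$target_h2_aut - cfg$target_h2_x))
    e <- stats::rnorm(n, 0, sig_e)
    y <- g_a + g_x + e

    ids <- sprintf("%s_F%04d", pops[ip], seq_len(n))
    all_dos[[ip]] <- dos
    all_samp[[ip]] <- data.frame(
      sample_id = ids, population = pops[ip], sex = "F",
      sire = sprintf("%s_S%03d", pops[ip], sire_of))
    all_y[[ip]] <- data.frame(sample_id = ids, trait = cfg$trait_name,
                              value = y)
    eff_list[[ip]] <- data.frame(population = pops[ip], id = variants$id,
                                 effect_std = eff)
    comp_list[[ip]] <- data.frame(
      population = pops[ip],
      sigma2_a = stats::var(g_a), sigma2_x = stats::var(g_x),
      sigma2_e = stats::var(e))
  }

  dos <- do.call(rbind, all_dos)
  samples <- do.call(rbind, all_samp)
  dm <- dosage_matrix(dos, variants, samples)
  pheno <- do.call(rbind, all_y)
  rownames(pheno) <- NULL
  comps <- do.call(rbind, comp_list)
  rownames(comps) <- NULL
  truth <- list(effects = do.call(rbind, eff_list),
                components = comps,
                planted_qtl = pq,
                targets = list(h2_aut = cfg$target_h2_aut,
                               h2_x = cfg$target_h2_x))
  list(dm = dm, pheno = pheno, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Convenience wrapper producing the dosage TSV (+ variant sidecar), the
#' phenotype TSV, and a truth JSON under a common prefix.
#'
#' @param sim result of \code{\link{simulate_population}}.
#' @param out_prefix path prefix; files are
#'   \code{<prefix>dosages.tsv}, \code{<prefix>pheno.tsv},
#'   \code{<prefix>truth.json}.
#' @return character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, out_prefix) {
  paths <- c(dosages = paste0(out_prefix, "dosages.tsv"),
             pheno = paste0(out_prefix, "pheno.tsv"),
             truth = paste0(out_prefix, "truth.json"))
  write_dosages(sim$dm, paths[["dosages"]])
  write_phenotypes(sim$pheno, paths[["pheno"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
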