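# Shared fixture builders; everything is generated in code at test time.

# Hand-built 4-sample x 3-variant dosage matrix
toy_dm <- function() {
  dosage_matrix(
    matrix(c(0, 1, 2, 1,
             2, 2, 0, 0,
             1, 0, 1, 2), nrow = 4, ncol = 3),
    data.frame(id = c("v1", "v2", "v3"), chrom = c("2", "2", "X"),
               pos = c(100L, 5000L, 200L), ref = "A", alt = "C",
               imputation_r2 = c(0.9, 0.4, NA)),
    data.frame(sample_id = paste0("S", 1:4)))
}

# Random polymorphic dosage matrix for numerical oracles
random_dm <- function(n, m, seed = 1, chrom = "2") {
  set.seed(seed)
  repeat {
    dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(seq_len(m),
                                                          each = n)]),
                  n, m)
    p <- colMeans(dos) / 2
    if (all(p > 0 & p < 1)) break
  }
  dosage_matrix(dos,
                data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                           pos = sort(sample.int(1e6, m)), ref = "A",
                           alt = "C"),
                paste0("S", seq_len(n)))
}

# Small simulated cohort reused across tests
small_sim <- function(seed = 5, n = 300, n_pop = 1, ...) {
  simulate_population(sim_config(n_populations = n_pop,
                                 n_females_per_pop = n,
                                 n_autosomal_variants = 250,
                                 n_x_variants = 180, seed = seed, ...))
}

# GRMs + aligned phenotype from a simulation (after sequence QC)
sim_inputs <- function(sim, population = NULL) {
  dm <- sim$dm
  if (!is.null(population)) {
    dm <- dm[which(dm$samples$population == population), ]
  }
  dm <- apply_variant_qc(dm, qc_thresholds(), "sequence_filter")$dm
  is_x <- dm$variants$chrom == "X"
  list(dm = dm,
       G_A = compute_grm(dm, which(!is_x), "autosomal"),
       G_X = compute_grm(dm, which(is_x), "X"),
       y = unname(phenotype_vector(sim$pheno, "YD",
                                   dm$samples$sample_id)))
}

# Identity-GRM helper for degenerate designs
identity_grm <- function(n, label = "I") {
  structure(list(values = diag(n), samples = paste0("S", seq_len(n)),
                 n_snps = 1L, snp_ids = NULL, snp_set_label = label),
            class = "grm_matrix")
}
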