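# Independent naive reference implementation of the six-step LD-peeling
# procedure, written directly from its description; shares no code with
# call_qtl.
naive_peel <- function(tab, dosages, thr = 7.3, half = 1e7, ld = 0.7) {
  out <- list()
  remaining <- tab
  iter <- 0
  while (nrow(remaining) > 0) {
    sig <- remaining[remaining$neglog10p >= thr, ]
    if (nrow(sig) == 0) break
    iter <- iter + 1
    sig <- sig[order(-sig$neglog10p, sig$pos, sig$id), ]
    lead <- sig[1, ]
    win <- remaining[abs(remaining$pos - lead$pos) <= half, ]
    r <- sapply(win$id, function(v)
      if (v == lead$id) 1 else cor(dosages[, lead$id], dosages[, v]))
    r[is.na(r)] <- 0
    ci <- win[abs(r) >= ld, ]
    rest <- win[abs(r) < ld, ]
    r_rest <- r[abs(r) < ld]
    drop_ids <- ci$id
    if (nrow(rest) > 0) {
      t_new <- (rest$b - lead$b * r_rest) / rest$se
      p_new <- 2 * pnorm(-abs(t_new))
      t_i <- rest$b / rest$se
      expl <- (-log10(p_new) < thr) & (sign(t_new) == sign(t_i))
      drop_ids <- c(drop_ids, rest$id[expl])
    }
    out[[iter]] <- data.frame(lead_id = lead$id, lead_bp = lead$pos,
                              ci_start = min(ci$pos), ci_end = max(ci$pos),
                              n_ci = nrow(ci), iteration = iter)
    remaining <- remaining[!(remaining$id %in% drop_ids), ]
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Simulated single-population chromosome scan with planted X QTL
planted_scan <- function(seed = 101, effects = c(0.30, 0.28, 0.26),
                         qtl_pos = c(2e7, 6e7, 1e8), n = 800) {
  pq <- data.frame(chrom = "X", pos = qtl_pos, effect = effects)
  sim <- simulate_population(sim_config(
    n_populations = 1, n_females_per_pop = n,
    n_autosomal_variants = 250, n_x_variants = 300,
    target_h2_aut = 0.15, target_h2_x = 0.01,
    planted_qtl = pq, seed = seed))
  inp <- sim_inputs(sim)
  dmx <- inp$dm[, which(inp$dm$variants$chrom == "X")]
  scan <- run_scan(dmx, inp$y, inp$G_A, trait = "YD", population = "POP1")
  list(scan = scan, dmx = dmx, pq = pq)
}
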