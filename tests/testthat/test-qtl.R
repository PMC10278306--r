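test_that("the Bonferroni threshold matches its closed form", {
  expect_equal(round(significance_threshold(0.05, 1e6), 1), 7.3)
  expect_equal(significance_threshold(0.5, 1), -log10(0.5),
               tolerance = 1e-12)
  expect_equal(significance_threshold(0.05, 54616), 6.038,
               tolerance = 1e-3)
  expect_error(significance_threshold(1.0, 10), "alpha")
  expect_error(significance_threshold(0, 10), "alpha")
})

test_that("the conditional statistic behaves at its limits", {
  # independence limit: r = 0 leaves the Wald statistic untouched
  cs <- conditional_statistic(0.3, 0.05, 0.4, 0)
  expect_equal(cs$T_new, cs$T_i)
  # perfect-LD shadow: identical effect in full LD is fully explained
  cs <- conditional_statistic(0.4, 0.05, 0.4, 1)
  expect_equal(cs$T_new, 0)
  expect_equal(cs$p_new, 1)
  # hand-computed case where conditioning flips the sign
  cs <- conditional_statistic(0.30, 0.05, 0.40, 0.8)
  expect_equal(cs$T_new, -0.4, tolerance = 1e-12)
  expect_true(sign(cs$T_new) != sign(cs$T_i))
  expect_error(conditional_statistic(0.3, 0, 0.4, 0.5), "positive")
})

test_that("sub-threshold scans yield no QTL", {
  tab <- data.frame(id = paste0("v", 1:5), chrom = "X",
                    pos = (1:5) * 1e6, b = 0.1, se = 0.05,
                    p = 10^-6.9, neglog10p = 6.9)
  dm <- random_dm(50, 5, seed = 1, chrom = "X")
  tab$id <- dm$variants$id
  tab$pos <- dm$variants$pos
  q <- call_qtl(tab, dm)
  expect_s3_class(q, "qtl_regions")
  expect_equal(nrow(q), 0)
})

test_that("one mutually-linked significant block gives exactly one region", {
  # four variants that are near-copies of each other (|r| ~ 1)
  set.seed(4)
  base <- rbinom(400, 2, 0.4)
  noise <- function() {
    x <- base
    i <- sample(400, 6)
    x[i] <- pmin(2, pmax(0, x[i] + sample(c(-1, 1), 6, TRUE)))
    x
  }
  dos <- cbind(base, noise(), noise(), noise())
  dm <- dosage_matrix(dos, data.frame(id = paste0("v", 1:4), chrom = "X",
                                      pos = c(1e6, 2e6, 3e6, 4e6),
                                      ref = "A", alt = "C"),
                      paste0("S", 1:400))
  tab <- data.frame(id = paste0("v", 1:4), chrom = "X",
                    pos = c(1e6, 2e6, 3e6, 4e6),
                    b = c(0.30, 0.28, 0.29, 0.31), se = 0.03,
                    p = 1e-20, neglog10p = 20)
  q <- call_qtl(tab, dm)
  expect_equal(nrow(q), 1)
  expect_equal(q$n_ci_variants, 4)
  expect_equal(q$ci_start_bp, 1e6)
  expect_equal(q$ci_end_bp, 4e6)
  expect_true(q$lead_bp >= q$ci_start_bp && q$lead_bp <= q$ci_end_bp)
})

test_that("peeling matches the naive reference on a planted chromosome", {
  ps <- planted_scan()
  q <- call_qtl(ps$scan, ps$dmx)
  ref <- naive_peel(ps$scan$stats, ps$dmx$dosages)
  expect_equal(nrow(q), nrow(ref))
  expect_identical(q$lead_id, ref$lead_id)
  expect_equal(q$ci_start_bp, ref$ci_start)
  expect_equal(q$ci_end_bp, ref$ci_end)
  expect_equal(q$n_ci_variants, ref$n_ci)
  # every lead is significant and inside its own interval
  expect_true(all(q$lead_neglog10p >= 7.3))
  expect_true(all(q$lead_bp >= q$ci_start_bp & q$lead_bp <= q$ci_end_bp))
})

test_that("reported leads are mutually unlinked or distant", {
  ps <- planted_scan(seed = 103)
  q <- call_qtl(ps$scan, ps$dmx)
  if (nrow(q) >= 2) {
    for (i in 1:(nrow(q) - 1)) for (j in (i + 1):nrow(q)) {
      r <- cor(ps$dmx$dosages[, q$lead_id[i]],
               ps$dmx$dosages[, q$lead_id[j]])
      dist <- abs(q$lead_bp[i] - q$lead_bp[j])
      expect_true(abs(r) < 0.7 || dist > 1e7)
    }
  }
})

test_that("raising the LD threshold never enlarges a lead's interval", {
  ps <- planted_scan(seed = 105)
  q1 <- call_qtl(ps$scan, ps$dmx, peeling_config(ci_ld_threshold = 0.5))
  q2 <- call_qtl(ps$scan, ps$dmx, peeling_config(ci_ld_threshold = 0.9))
  shared <- intersect(q1$lead_id, q2$lead_id)
  for (id in shared) {
    expect_lte(q2$n_ci_variants[q2$lead_id == id],
               q1$n_ci_variants[q1$lead_id == id])
  }
})

test_that("the trace log audits explained-variant removals", {
  ps <- planted_scan(seed = 107)
  tr <- file.path(withr::local_tempdir(), "trace.log")
  q <- call_qtl(ps$scan, ps$dmx, trace = tr)
  expect_true(file.exists(tr))
  lines <- readLines(tr)
  expect_true(length(lines) >= nrow(q))
  expect_true(all(grepl("^iter", lines)))
})

test_that("scan/reference mismatches and multi-chromosome input error", {
  ps <- planted_scan(seed = 109, n = 300)
  bad <- ps$scan$stats
  bad$id[1] <- "phantom"
  expect_error(call_qtl(bad, ps$dmx), "missing from the LD reference")
  two <- ps$scan$stats
  two$chrom[1] <- "2"
  expect_error(call_qtl(two, ps$dmx), "single chromosome")
})
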