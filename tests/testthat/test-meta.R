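# Minimal study table builder (data.frame input path of fixed_effects_meta)
study_tab <- function(b, se, pos = seq_along(b), chrom = "X",
                      ref = "A", alt = "C", freq = 0.3, n = 1000) {
  data.frame(id = paste0(chrom, ":", pos), chrom = chrom, pos = pos,
             ref = ref, alt = alt, freq = freq, b = b, se = se,
             p = 2 * pnorm(-abs(b / se)), n = n)
}

test_that("a single study passes through unchanged", {
  s <- study_tab(b = c(0.2, -0.1), se = c(0.05, 0.08))
  m <- fixed_effects_meta(list(s))
  expect_equal(m$b_meta, s$b)
  expect_equal(m$se_meta, s$se)
  expect_equal(m$p, s$p, tolerance = 1e-12)
  expect_equal(m$direction, c("+", "-"))
})

test_that("two identical studies halve the variance", {
  s <- study_tab(b = 0.3, se = 0.1)
  m <- fixed_effects_meta(list(s, s))
  expect_equal(m$b_meta, 0.3, tolerance = 1e-12)
  expect_equal(m$se_meta, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$direction, "++")
})

test_that("inverse-variance weighting matches the hand oracle and metafor", {
  b <- c(0.2, 0.1, -0.1)
  se <- c(0.1, 0.2, 0.4)
  studies <- lapply(seq_along(b), function(i)
    study_tab(b = b[i], se = se[i]))
  m <- fixed_effects_meta(studies)
  w <- 1 / se^2
  expect_equal(m$b_meta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m$se_meta, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(m$z, m$b_meta / m$se_meta, tolerance = 1e-12)
  expect_equal(m$direction, "++-")
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = b, sei = se, method = "FE")
  expect_equal(m$b_meta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se_meta, rma$se, tolerance = 1e-10)
})

test_that("statistics are invariant to study order", {
  s1 <- study_tab(b = c(0.2, 0.05), se = c(0.1, 0.2))
  s2 <- study_tab(b = c(-0.1, 0.15), se = c(0.15, 0.1))
  m12 <- fixed_effects_meta(list(s1, s2))
  m21 <- fixed_effects_meta(list(s2, s1))
  expect_equal(m12$p, m21$p, tolerance = 1e-12)
  expect_equal(m12$se_meta, m21$se_meta, tolerance = 1e-12)
  expect_equal(abs(m12$b_meta), abs(m21$b_meta), tolerance = 1e-12)
  # direction strings follow the declared study order
  reversed <- vapply(strsplit(m12$direction, ""),
                     function(d) paste(rev(d), collapse = ""), "")
  expect_equal(m21$direction, reversed)
})

test_that("partial coverage combines the available subset with '?' marks", {
  s1 <- study_tab(b = c(0.2, 0.1), se = c(0.1, 0.1), pos = c(1, 2))
  s2 <- study_tab(b = 0.3, se = 0.1, pos = 2)
  m <- fixed_effects_meta(list(s1, s2))
  m1 <- m[m$pos == 1, ]
  expect_equal(m1$n_studies, 1)
  expect_equal(m1$direction, "+?")
  expect_equal(m1$b_meta, 0.2)
  m2 <- m[m$pos == 2, ]
  expect_equal(m2$n_studies, 2)
  expect_equal(m2$b_meta, 0.2, tolerance = 1e-12)  # equal weights
})

test_that("swapped alleles are flipped; irreconcilable ones dropped", {
  s1 <- study_tab(b = 0.2, se = 0.1, ref = "A", alt = "C", freq = 0.3)
  s2 <- study_tab(b = -0.2, se = 0.1, ref = "C", alt = "A", freq = 0.7)
  m <- fixed_effects_meta(list(s1, s2))
  expect_equal(m$b_meta, 0.2, tolerance = 1e-12)
  expect_equal(m$direction, "++")

  s3 <- study_tab(b = 0.2, se = 0.1, ref = "G", alt = "T")
  expect_warning(m2 <- fixed_effects_meta(list(s1, s3)),
                 "irreconcilable")
  expect_equal(nrow(m2), 0)
})

test_that("the sample-size scheme reproduces the weighted z formula", {
  s1 <- study_tab(b = 0.2, se = 0.1, n = 400)
  s2 <- study_tab(b = 0.1, se = 0.15, n = 900)
  m <- fixed_effects_meta(list(s1, s2), scheme = "samplesize")
  z <- c(0.2 / 0.1, 0.1 / 0.15)
  zw <- sum(sqrt(c(400, 900)) * z) / sqrt(400 + 900)
  expect_equal(m$z, zw, tolerance = 1e-12)
  expect_true(is.na(m$b_meta))
})

test_that("meta equals GLS on stacked data when studies share the effect", {
  # one shared causal variant, three cohorts: meta b equals the GLS
  # (weighted least squares) estimate on the stacked standardized data
  set.seed(3)
  beta <- 0.15
  tabs <- list(); xs <- list(); ys <- list()
  for (k in 1:3) {
    n <- c(300, 500, 400)[k]
    x <- rbinom(n, 2, 0.4)
    y <- beta * x + rnorm(n)
    fit <- summary(lm(y ~ x))$coefficients
    tabs[[k]] <- study_tab(b = fit[2, 1], se = fit[2, 2], n = n)
    xs[[k]] <- x; ys[[k]] <- y
  }
  m <- fixed_effects_meta(tabs)
  # GLS oracle: per-study weights equal inverse sampling variances
  w <- 1 / sapply(tabs, function(t) t$se^2)
  bg <- sum(w * sapply(tabs, function(t) t$b)) / sum(w)
  expect_equal(m$b_meta, bg, tolerance = 1e-6)
  expect_lt(abs(m$b_meta - beta), 3 * m$se_meta)
})
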