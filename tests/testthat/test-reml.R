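test_that("heritability arithmetic reproduces the published partition", {
  # Abondance milk-yield components back out the printed row exactly
  h <- heritability_from_components(c(0.315, 0.009, 0.676))
  expect_equal(h$h2, 0.324)
  expect_equal(h$h2_aut, 0.315)
  expect_equal(h$h2_x, 0.009)
  expect_equal(h$h2, h$h2_aut + h$h2_x)  # exact by construction

  expect_equal(heritability_from_components(c(0, 0, 1))$h2, 0)
  h2 <- heritability_from_components(c(1, 1, 2))
  expect_equal(h2$h2, 0.5)
  expect_equal(h2$h2_aut, 0.25)
  expect_equal(h2$h2_x, 0.25)
  expect_error(heritability_from_components(c(0, 0, 0)), "positive")
})

test_that("pure-noise phenotypes drive both genetic components to the boundary", {
  sim <- small_sim(seed = 21, n = 400, target_h2_aut = 0, target_h2_x = 0)
  inp <- sim_inputs(sim)
  vc <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X)
  expect_lt(vc$sigma2_a, 0.08)
  expect_lt(vc$sigma2_x, 0.08)
  expect_equal(vc$sigma2_e, 1, tolerance = 0.15)
  h <- heritability_from_components(vc)
  expect_lt(h$h2, 0.12)
})

test_that("non-identifiable designs are flagged, not resolved arbitrarily", {
  set.seed(2)
  n <- 80
  y <- rnorm(n)
  vc <- fit_reml_two_components(y, identity_grm(n, "A"),
                                identity_grm(n, "X"))
  # proportional GRMs: the split sigma2_a vs sigma2_x is not identifiable
  expect_true(!vc$converged || any(vc$fixed_at_zero))
})

test_that("estimates are invariant to phenotype rescaling", {
  sim <- small_sim(seed = 13, n = 350)
  inp <- sim_inputs(sim)
  vc1 <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X)
  vc2 <- fit_reml_two_components(inp$y * 3, inp$G_A, inp$G_X)
  expect_equal(vc2$sigma2_a, 9 * vc1$sigma2_a, tolerance = 1e-6)
  expect_equal(vc2$sigma2_x, 9 * vc1$sigma2_x, tolerance = 1e-6)
  expect_equal(vc2$sigma2_e, 9 * vc1$sigma2_e, tolerance = 1e-6)
  h1 <- heritability_from_components(vc1)
  h2 <- heritability_from_components(vc2)
  expect_equal(h1$h2_aut, h2$h2_aut, tolerance = 1e-8)
  expect_equal(h1$h2_x, h2$h2_x, tolerance = 1e-8)
})

test_that("restricted log-likelihood never decreases across EM steps", {
  sim <- small_sim(seed = 31, n = 300)
  inp <- sim_inputs(sim)
  vc <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X, init = "equal")
  tr <- vc$trace
  dl <- diff(tr$loglik)
  em_after <- tr$step[-1] == "EM"
  if (any(em_after)) expect_true(all(dl[em_after] > -1e-6))
  # and the full trajectory ends no lower than it starts
  expect_gte(tr$loglik[nrow(tr)], tr$loglik[1] - 1e-6)
  # both initializations reach the same optimum
  vc_he <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X, init = "he")
  expect_equal(vc$loglik, vc_he$loglik, tolerance = 1e-5)
  expect_equal(vc$sigma2_a, vc_he$sigma2_a, tolerance = 1e-3)
})

test_that("standard errors are positive and delta-method consistent", {
  sim <- small_sim(seed = 17, n = 400, target_h2_aut = 0.35,
                   target_h2_x = 0.05)
  inp <- sim_inputs(sim)
  vc <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X)
  expect_gt(vc$se_sigma2_a, 0)
  expect_gt(vc$se_sigma2_e, 0)
  h <- heritability_from_components(vc)
  expect_gt(h$se_h2_aut, 0)
  expect_gte(h$se_h2_x, 0)
  # delta method recomputed by hand from the stored covariance
  comp <- c(vc$sigma2_a, vc$sigma2_x, vc$sigma2_e)
  tot <- sum(comp)
  g <- c(tot - comp[1], -comp[1], -comp[1]) / tot^2
  expect_equal(h$se_h2_aut, sqrt(drop(t(g) %*% vc$cov %*% g)),
               tolerance = 1e-12)
})

test_that("REML recovers a planted variance split in a small simulation study", {
  est <- t(sapply(1:12, function(s) {
    sim <- simulate_population(sim_config(
      n_populations = 1, n_females_per_pop = 500,
      n_autosomal_variants = 300, n_x_variants = 200,
      target_h2_aut = 0.40, target_h2_x = 0.10, seed = 400 + s))
    inp <- sim_inputs(sim)
    vc <- fit_reml_two_components(inp$y, inp$G_A, inp$G_X)
    h <- heritability_from_components(vc)
    c(h$h2_aut, h$h2_x, vc$converged)
  }))
  expect_true(all(est[, 3] == 1))
  mc_se <- apply(est[, 1:2], 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.40), 2.5 * mc_se[1] + 0.01)
  expect_lt(abs(mean(est[, 2]) - 0.10), 2.5 * mc_se[2] + 0.01)
})

test_that("input contracts are enforced", {
  sim <- small_sim(seed = 23, n = 60)
  inp <- sim_inputs(sim)
  expect_error(fit_reml_two_components(inp$y[1:50], inp$G_A, inp$G_X),
               "length")
  expect_error(fit_reml_two_components(rnorm(20), identity_grm(20),
                                       identity_grm(20)),
               "at least 30")
})
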