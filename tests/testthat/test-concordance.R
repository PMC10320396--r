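test_that("p-value transform and mixture-scale estimation behave", {
  expect_equal(transform_pvalues(1), 0)
  expect_equal(transform_pvalues(exp(-1)), 2)
  expect_equal(transform_pvalues(0.01), -2 * log(0.01))
  expect_error(transform_pvalues(c(0.5, 0)), "\\(0, 1\\]")

  # all-null column: scale stays above its floor
  set.seed(5)
  t_null <- transform_pvalues(runif(1e4))
  fit <- fit_study_mixture(t_null, alt_prop = 1e-3)
  expect_gt(fit$a, 1)
  # constant zero column hits the floor exactly
  expect_warning(f0 <- fit_study_mixture(rep(0, 100), alt_prop = 1e-3),
                 "fewer than 5")
  expect_equal(f0$a, 1 + 1e-6)
  # planted alternative with true scale 8 is recovered to the right order;
  # the top-tail moment estimate is biased upward by extreme null order
  # statistics, so the across-seed average is what lands in band
  as_hat <- vapply(1:10, function(s) {
    sim <- simulate_pattern_pvalues(2e4, 1, c(1 - 1e-3, 1e-3), alt_scale = 8,
                                    seed = s)
    fit_study_mixture(transform_pvalues(sim$P[, 1]), 1e-3)$a
  }, numeric(1))
  expect_gte(mean(as_hat), 5)
  expect_lte(mean(as_hat), 12)
})

test_that("EM: all-null data concentrates on the null pattern, LL monotone", {
  sim <- simulate_pattern_pvalues(5e3, 2, c(1, 0, 0, 0), seed = 2)
  fit <- fit_concordance(sim$P, alt_props = 1e-3)
  expect_gte(fit$pi[1], 0.98)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_true(fit$converged)
})

test_that("EM recovers planted pattern weights and is a fixed point at truth", {
  probs <- c(0.90, 0.04, 0.04, 0.02)
  errs <- vapply(1:5, function(s) {
    sim <- simulate_pattern_pvalues(2e4, 2, probs, alt_scale = 10, seed = 100 + s)
    # fitting prior set to the generator's marginal alternative fraction
    marg <- as.vector(probs %*% xwasmr:::pattern_matrix(2))
    fit <- fit_concordance(sim$P, alt_props = marg)
    max(abs(fit$pi - probs))
  }, numeric(1))
  expect_lt(max(errs), 0.02)

  # one EM iteration from the truth barely moves the weights (fixed point)
  sim <- simulate_pattern_pvalues(1e5, 2, probs, alt_scale = 10, seed = 31)
  T <- transform_pvalues(sim$P)
  em1 <- em_pattern_weights(T, a = c(10, 10), tol = Inf, max_iter = 1L,
                            init = probs)
  # tol = Inf stops after the first E/M pass started at the truth
  expect_lt(max(abs(em1$pi - probs)), 0.005)
})

test_that("posteriors: rows normalized, marginal PP, strong genes called", {
  probs <- c(0.90, rep(0.10 / 7, 7))
  sim <- simulate_pattern_pvalues(5e3, 3, probs, alt_scale = 10, seed = 7)
  fit <- fit_concordance(sim$P, alt_props = 0.05)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  expect_true(all(fit$PP >= 0 & fit$PP <= 1))
  expect_lt(abs(sum(fit$pi) - 1), 1e-9)

  # a gene overwhelming in all studies is called everywhere
  P2 <- rbind(sim$P, strong = c(1e-30, 1e-30, 1e-30))
  fit2 <- fit_concordance(P2, alt_props = 0.05)
  expect_true(all(fit2$PP[nrow(P2), ] > 0.95))
  # a gene with p = 1 everywhere is never called under a mostly-null fit
  P3 <- rbind(sim$P, flat = c(1, 1, 1))
  fit3 <- fit_concordance(P3, alt_props = 0.05)
  expect_true(all(fit3$PP[nrow(P3), ] < 0.95))
})

test_that("permuting study order permutes PP columns identically", {
  probs <- c(0.85, 0.05, 0.05, 0.05)
  sim <- simulate_pattern_pvalues(3e3, 2, probs, alt_scale = 8, seed = 13)
  fit_ab <- fit_concordance(sim$P, alt_props = 0.05)
  fit_ba <- fit_concordance(sim$P[, c(2, 1)], alt_props = 0.05)
  expect_equal(fit_ba$PP[, "study1"], fit_ab$PP[, "study1"], tolerance = 1e-8)
  expect_equal(fit_ba$PP[, "study2"], fit_ab$PP[, "study2"], tolerance = 1e-8)
})

test_that("J = 1 reduces to the closed-form two-component posterior", {
  sim <- simulate_pattern_pvalues(5e3, 1, c(0.95, 0.05), alt_scale = 10, seed = 3)
  T <- transform_pvalues(sim$P)
  a <- fit_study_mixture(T[, 1], 0.05)$a
  em <- em_pattern_weights(T, a = a)
  pi1 <- em$pi[2]
  f0 <- exp(-T[, 1] / 2) / 2
  f1 <- exp(-T[, 1] / (2 * a)) / (2 * a)
  closed <- pi1 * f1 / (pi1 * f1 + (1 - pi1) * f0)
  PP <- em$posterior %*% em$patterns
  expect_equal(as.vector(PP), unname(closed), tolerance = 1e-9)
})

test_that("tidy/glance/sweep summarize a fit", {
  probs <- c(0.9, 0.04, 0.04, 0.02)
  sim <- simulate_pattern_pvalues(2e3, 2, probs, alt_scale = 10, seed = 9)
  fit <- fit_concordance(sim$P, alt_props = 0.05)
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_studies, 2L)

  sw <- suppressWarnings(sweep_alt_props(sim$P, grid = c(1e-3, 1e-2, 5e-2)))
  expect_equal(nrow(sw), 3L)
  # larger priors admit at least as many calls on this fixture
  expect_true(all(diff(sw$n_significant) >= 0))
})
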