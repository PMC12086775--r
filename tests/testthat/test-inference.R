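test_that("pooled summary statistics match hand computation", {
  d <- dose_design(c(0, 1), c(2, 2))
  st <- summarize_trial(data.frame(dose = c(0, 0, 1, 1),
                                   response = c(0, 2, 1, 3)), d)
  expect_equal(st$means, c(1, 2))
  expect_equal(st$s2, 2)
  expect_equal(st$df, 2L)
  # case design: df = N - k - 1 = 396
  d4 <- case_design()
  scen <- scenario(d4, means = rep(0, 4), seed = 5)
  st4 <- summarize_trial(simulate_trial(scen, 1), d4)
  expect_equal(st4$df, 396L)
})

test_that("degenerate trial data is rejected", {
  d <- dose_design(c(0, 1), c(2, 2))
  expect_error(
    summarize_trial(data.frame(dose = c(0, 0, 1, 1), response = rep(1, 4)), d),
    "zero")
  expect_error(
    summarize_trial(data.frame(dose = c(0, 1, 1), response = c(1, 2, 3)), d),
    "at least 2")
})

test_that("contrast statistics match their definition and invariances", {
  d <- dose_design(c(0, 1), c(100, 100))
  st <- summary_stats(means = c(0, 1), s2 = 1, df = 198, design = d)
  cc <- c(-1, 1) / sqrt(2)
  expect_equal(as.numeric(contrast_statistics(st, cc)),
               (1 / sqrt(2)) / sqrt(1 / 100), tolerance = 1e-12)
  # flat means give 0 for any zero-sum contrast
  st0 <- summary_stats(means = c(3, 3), s2 = 2, df = 198, design = d)
  expect_equal(as.numeric(contrast_statistics(st0, cc)), 0)
  # scale invariance: scaling responses by c scales means and s together
  stc <- summary_stats(means = c(0, 5), s2 = 25, df = 198, design = d)
  expect_equal(contrast_statistics(stc, cc), contrast_statistics(st, cc))
})

test_that("adjusted p-values reduce to known closed forms", {
  # univariate: one-sided t, normal limit
  expect_equal(as.numeric(mvt_pvalues(1.96, matrix(1), df = 1e6)),
               0.025, tolerance = 1e-4)
  # two independent statistics, large df: 1 - pnorm(t)^2
  q <- mvt_pvalues(c(2, 2), diag(2), df = 1e5)
  expect_equal(as.numeric(q), rep(1 - stats::pnorm(2)^2, 2), tolerance = 2e-4)
  expect_lte(attr(q, "error"), 1e-4)
  # perfectly correlated duplicate collapses to the univariate p
  R <- matrix(1, 2, 2)
  expect_equal(as.numeric(mvt_pvalues(c(2.1, 2.1), R, df = 50)),
               rep(stats::pt(2.1, 50, lower.tail = FALSE), 2),
               tolerance = 1e-12)
  expect_error(mvt_pvalues(c(1, 1), matrix(c(1, 2, 2, 1), 2), df = 10),
               "positive semidefinite|invalid")
})

test_that("critical values match univariate quantiles and a Monte-Carlo
           oracle", {
  expect_equal(mvt_critical(matrix(1), df = 30, alpha = 0.025),
               stats::qt(0.975, 30))
  expect_equal(mvt_critical(matrix(1), df = 7, alpha = 0.5), 0,
               tolerance = 1e-12)
  # 3-dim equicorrelated 0.5 (balanced many-to-one), df 396
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  crit <- mvt_critical(R, df = 396, alpha = 0.025)
  mc <- mc_maxt_quantile(0.5, 3, 396, 0.025)
  expect_lt(abs(crit - mc), 0.01)
})

test_that("adjusted p-values and critical values are dual", {
  set.seed(41)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    d <- random_design(k)
    cmat <- sapply(1:sample(2:5, 1), function(j)
      optimal_contrast(random_profile(k), d))
    R <- contrast_correlation(cmat, d)
    df <- sample(20:400, 1)
    alpha <- stats::runif(1, 0.01, 0.2)
    crit <- mvt_critical(R, df, alpha)
    p_at_crit <- as.numeric(mvt_pvalues(rep(crit, ncol(R)), R, df)[1])
    expect_lt(abs(p_at_crit - alpha), 5e-4)
    # rejection by min p < alpha iff max statistic >= critical value
    tstat <- stats::rnorm(ncol(R), 1.5, 1)
    q <- mvt_pvalues(tstat, R, df)
    if (abs(max(tstat) - crit) > 5e-3)  # away from the knife edge
      expect_equal(min(q) < alpha, max(tstat) >= crit)
  }
})

test_that("adjusted p-values are monotone in the statistic and in the
           family size", {
  R2 <- diag(2); R3 <- diag(3)
  q_small <- as.numeric(mvt_pvalues(c(1.5, 2.5), R2, 100))
  expect_gt(q_small[1], q_small[2])
  # adding an independent contrast can only increase the adjusted p
  q2 <- as.numeric(mvt_pvalues(c(2, 2), R2, 100)[1])
  q3 <- as.numeric(mvt_pvalues(c(2, 2, 2), R3, 100)[1])
  expect_gt(q3, q2)
})

test_that("null calibration: the maxT test rejects at its nominal rate", {
  # flat truth on the case design; decisions via the precomputed plan
  d <- case_design()
  plan <- closed_mcpmod_plan(d, default_candidate_set(), constrained = TRUE,
                             alpha = 0.025)
  scen <- scenario(d, means = rep(0, 4), sigma = 1, seed = 314)
  sm <- simulate_summaries(scen, 4000)
  dec <- plan_decisions(plan, sm$means, sm$s)
  rate <- mean(dec$intersection[, 1])  # global maxT test
  se <- sqrt(0.025 * 0.975 / 4000)
  expect_lt(abs(rate - 0.025), 3 * se)
})
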