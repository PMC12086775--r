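test_that("local levels reproduce the reference intersections of the
           symmetric two-endpoint graph", {
  g <- two_endpoint_graph(3)
  a <- 0.025
  lv <- function(I) unname(local_levels(g, I, alpha = a))
  # all primary and/or secondary hypotheses involved
  expect_equal(lv(c("H11", "H12", "H13", "H21", "H22", "H23")),
               c(a/3, a/3, a/3, 0, 0, 0))
  # all secondary
  expect_equal(lv(c("H21", "H22", "H23")), c(a/3, a/3, a/3))
  # two primary and all secondary
  expect_equal(lv(c("H11", "H12", "H21", "H22", "H23")),
               c(a/3, a/3, 0, 0, a/3))
  # two primary and their two secondary
  expect_equal(lv(c("H11", "H12", "H21", "H22")), c(a/2, a/2, 0, 0))
  # a primary and all secondary
  expect_equal(lv(c("H11", "H21", "H22", "H23")), c(a/3, 0, a/3, a/3))
  # a primary and two secondary
  expect_equal(lv(c("H11", "H21", "H23")), c(a/2, 0, a/2))
  # a primary and a secondary of another dose
  expect_equal(lv(c("H11", "H23")), c(a/2, a/2))
})

test_that("levels are conserved, never exceed alpha, and ignore removal
           order", {
  g <- two_endpoint_graph(3)
  labels <- g$labels
  for (b in seq_len(2^6 - 1)) {
    I <- labels[as.logical(bitwAnd(b, 2^(0:5)))]
    lv <- local_levels(g, I)
    expect_true(all(lv >= -1e-12))
    expect_lte(sum(lv), 1 + 1e-9)
    # no secondary level while every primary hypothesis is present
    if (all(c("H11", "H12", "H13") %in% I))
      expect_equal(unname(lv[intersect(I, c("H21", "H22", "H23"))]),
                   rep(0, length(intersect(I, c("H21", "H22", "H23")))))
  }
  # removal order invariance: 24 random permutations of the removal order,
  # evaluated with an independent straight-line implementation
  I <- c("H12", "H21")
  out <- setdiff(labels, I)
  ref <- local_levels(g, I)
  set.seed(3)
  for (r in 1:24) {
    lv <- local_levels_ordered(g, I, sample(out))
    expect_equal(lv, ref, tolerance = 1e-12)
  }
})

test_that("the generalized graph with edge weight x stays level-conserving", {
  for (x in c(0, 0.3, 0.7, 1)) {
    g <- two_endpoint_graph(3, x = x)
    expect_equal(sum(g$weights), 1)
    expect_true(all(rowSums(g$transitions) <= 1 + 1e-12))
    # full primary cascade still spends the whole level on primaries
    lv <- local_levels(g, c("H11", "H12", "H13"))
    expect_equal(sum(lv), 1, tolerance = 1e-12)
  }
})

test_that("two-endpoint closure: k = 1 is hierarchical testing at full
           level", {
  d <- dose_design(c(0, 1), c(60, 60))
  g <- two_endpoint_graph(1)
  set.seed(10)
  dat1 <- data.frame(dose = rep(c(0, 1), each = 60),
                     response = c(rnorm(60), rnorm(60, 0.6)))
  dat2 <- data.frame(dose = rep(c(0, 1), each = 60),
                     response = c(rnorm(60), rnorm(60, 0.5)))
  res <- closed_graphical_mcpmod(dat1, dat2, d, default_candidate_set(),
                                 g, alpha = 0.025)
  p1 <- pairwise_t_pvalues(summarize_trial(dat1, d), d)
  p2 <- pairwise_t_pvalues(summarize_trial(dat2, d), d)
  expect_equal(res$elementary$adjusted_p[1], p1, tolerance = 1e-10)
  expect_equal(res$elementary$adjusted_p[2], max(p1, p2), tolerance = 1e-10)
})

test_that("secondary hypotheses are rejected only after their own-dose
           primary", {
  d <- case_design(50L)
  models <- default_candidate_set()
  g <- two_endpoint_graph(3)
  scen1 <- scenario(d, candidate_model("emax", ed50 = 0.2), effect = 1.2,
                    seed = 61)
  scen2 <- scenario(d, candidate_model("emax", ed50 = 0.2), effect = 0.8,
                    seed = 62)
  n_secondary <- 0L
  for (r in 1:5) {
    res <- closed_graphical_mcpmod(simulate_trial(scen1, r),
                                   simulate_trial(scen2, r), d, models, g)
    rej <- res$elementary$reject
    names(rej) <- res$elementary$hypothesis
    for (i in 1:3) {
      expect_true(!rej[paste0("H2", i)] || rej[paste0("H1", i)])
      n_secondary <- n_secondary + rej[paste0("H2", i)]
    }
  }
  # the property must have been exercised, not vacuously true
  expect_gt(n_secondary, 0L)
})

test_that("graphical closure equals a direct per-intersection evaluation", {
  d <- case_design(25L)
  models <- default_candidate_set()
  g <- two_endpoint_graph(3)
  scen1 <- scenario(d, candidate_model("emax", ed50 = 0.2), effect = 0.8,
                    seed = 71)
  scen2 <- scenario(d, means = c(0, 0, 0.2, 0.5), seed = 72)
  dat1 <- simulate_trial(scen1, 1)
  dat2 <- simulate_trial(scen2, 1)
  res <- closed_graphical_mcpmod(dat1, dat2, d, models, g, alpha = 0.025)
  st1 <- summarize_trial(dat1, d)
  st2 <- summarize_trial(dat2, d)
  labels <- g$labels
  # brute-force: recompute every intersection with the standalone tester
  reject_oracle <- logical(length(labels))
  for (j in seq_along(labels)) {
    all_reject <- TRUE
    for (b in seq_len(2^6 - 1)) {
      I <- labels[as.logical(bitwAnd(b, 2^(0:5)))]
      if (!(labels[j] %in% I)) next
      tst <- test_intersection_graphical(I, st1, st2, d, models, g, 0.025)
      if (!tst$reject) { all_reject <- FALSE; break }
    }
    reject_oracle[j] <- all_reject
  }
  expect_equal(res$elementary$reject, reject_oracle)
})

test_that("plan-based two-endpoint decisions match the full procedure and
           control the familywise error under the complete null", {
  d <- case_design()
  models <- default_candidate_set()
  g <- two_endpoint_graph(3)
  plan <- closed_graphical_plan(d, models, g, alpha = 0.025)

  scen1 <- scenario(d, candidate_model("emax", ed50 = 0.05), effect = 0.5,
                    seed = 81)
  scen2 <- scenario(d, means = rep(0, 4), seed = 82)
  dat1 <- simulate_trial(scen1, 1)
  dat2 <- simulate_trial(scen2, 1)
  full <- closed_graphical_mcpmod(dat1, dat2, d, models, g)
  st1 <- summarize_trial(dat1, d)
  st2 <- summarize_trial(dat2, d)
  dec <- graphical_decisions(plan, st1$means, st1$s, st2$means, st2$s)
  expect_equal(as.logical(dec), full$elementary$reject)

  # complete null on both endpoints: FWER <= alpha + 3 SE
  null1 <- scenario(d, means = rep(0, 4), seed = 83)
  null2 <- scenario(d, means = rep(0, 4), seed = 84)
  nsim <- 2000
  sm1 <- simulate_summaries(null1, nsim)
  sm2 <- simulate_summaries(null2, nsim)
  rej <- graphical_decisions(plan, sm1$means, sm1$s, sm2$means, sm2$s)
  fwer <- mean(rowSums(rej) > 0)
  expect_lte(fwer, 0.025 + 3 * sqrt(0.025 * 0.975 / nsim))
})
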