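test_that("intersection enumeration covers all nonempty subsets in order", {
  expect_equal(enumerate_intersections(1), list(1L))
  expect_equal(enumerate_intersections(2), list(1:2, 1L, 2L))
  e3 <- enumerate_intersections(3)
  expect_length(e3, 7)
  expect_equal(e3[[1]], 1:3)
  expect_equal(vapply(e3, length, integer(1)), c(3, 2, 2, 2, 1, 1, 1))
  expect_error(enumerate_intersections(0), "1..15")
  expect_error(enumerate_intersections(16), "1..15")
})

test_that("singleton intersections reduce to the one-sided two-sample t", {
  fx <- make_fixture(3)
  st <- summarize_trial(fx$data, fx$design)
  p_t <- pairwise_t_pvalues(st, fx$design)
  for (i in 1:3) {
    for (constrained in c(TRUE, FALSE)) {
      res <- test_intersection(i, st, fx$design, fx$models, constrained)
      expect_equal(res$p_value, p_t[i], tolerance = 1e-12)
      expect_equal(res$adjusted_p, rep(p_t[i], 5), tolerance = 1e-12)
    }
  }
})

test_that("the row-minimum is the intersection p-value and the global test
           gates the closure", {
  fx <- make_fixture(4)
  for (rep in list(fx$constrained, fx$unconstrained)) {
    itab <- rep$intersection_table
    mods <- names(fx$models)
    expect_equal(itab$p_value, apply(itab[mods], 1, min))
    expect_equal(rep$global_p, itab$p_value[1])
    # closed adjusted p of every elementary hypothesis >= global p
    expect_true(all(rep$elementary$adjusted_p >= rep$global_p - 1e-12))
    # monotonicity: elementary adjusted p >= p of every containing intersection
    for (i in 1:3) {
      contains <- vapply(rep$intersections, function(r) i %in% r$intersection,
                         logical(1))
      expect_equal(rep$elementary$adjusted_p[i],
                   max(itab$p_value[contains]))
      expect_equal(rep$elementary$reject[i], all(itab$reject[contains]))
    }
  }
})

test_that("k = 1 closed test is the one-sided two-sample t-test", {
  d <- dose_design(c(0, 1), c(40, 40))
  set.seed(8)
  dat <- data.frame(dose = rep(c(0, 1), each = 40),
                    response = c(rnorm(40), rnorm(40, 0.5)))
  res <- closed_mcpmod(dat, d, default_candidate_set(), alpha = 0.025)
  tt <- stats::t.test(response ~ dose, dat, alternative = "less",
                      var.equal = TRUE)
  expect_equal(res$global_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$elementary$adjusted_p, tt$p.value, tolerance = 1e-10)
})

test_that("closed test equals an independent brute-force closure", {
  for (seed in c(1, 7, 202)) {
    fx <- make_fixture(seed)
    for (constrained in c(TRUE, FALSE)) {
      res <- if (constrained) fx$constrained else fx$unconstrained
      orc <- oracle_closed(fx$data, fx$design, fx$models, constrained, 0.025)
      expect_equal(res$elementary$reject, orc$elementary_reject,
                   info = sprintf("seed %d constrained %s", seed, constrained))
      expect_lt(max(abs(res$elementary$adjusted_p - orc$elementary_p)),
                5e-4)
      expect_lt(max(abs(res$intersection_table$p_value - orc$p_I)), 5e-4)
    }
  }
})

test_that("plan-based decisions agree with the full closed test", {
  fx <- make_fixture(12)
  st <- summarize_trial(fx$data, fx$design)
  for (constrained in c(TRUE, FALSE)) {
    plan <- closed_mcpmod_plan(fx$design, fx$models, constrained, 0.025)
    dec <- plan_decisions(plan, st$means, st$s)
    full <- if (constrained) fx$constrained else fx$unconstrained
    expect_equal(as.logical(dec$elementary), full$elementary$reject)
    expect_equal(as.logical(dec$intersection),
                 full$intersection_table$reject)
  }
})

test_that("no elementary rejection without a global dose-response signal", {
  d <- case_design(10L)
  scen <- scenario(d, means = rep(0, 4), seed = 99)
  found <- FALSE
  for (r in 1:20) {
    res <- closed_mcpmod(simulate_trial(scen, r), d, default_candidate_set())
    if (!res$intersection_table$reject[1]) {
      found <- TRUE
      expect_false(any(res$elementary$reject))
    }
  }
  expect_true(found)
})

test_that("the unconstrained variant warns about unproven strong control", {
  fx <- make_fixture(2)
  expect_warning(
    closed_mcpmod(fx$data, fx$design, fx$models, constrained = FALSE),
    "strong familywise error control")
})
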