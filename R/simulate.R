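# Trial data generator and operating-characteristics study: rejection
# probabilities (RAO, per-hypothesis power, AVE/k) per scenario and
# procedure, with common random numbers across procedures.

.substream_seed <- function(master, scenario = 0L, replicate = 1L) {
  as.integer((as.numeric(master) %% 1e6 * 1009 +
              as.numeric(scenario) * 1000003 +
              as.numeric(replicate) * 7919) %% 2147483629)
}

#' Simulation scenario
#'
#' Defines one data-generating configuration: normal responses around a true
#' mean profile, either a candidate model scaled to a maximum `effect`
#' (effect 0 at placebo, maximum effect at the dose of maximum efficacy) or
#' an explicit `means` vector.
#'
#' @param design A [dose_design()].
#' @param model Optional `candidate_model` giving the true shape.
#' @param effect Maximum treatment effect for `model` (response units).
#' @param means Explicit true arm means (overrides `model`/`effect`).
#' @param sigma Residual standard deviation (> 0), default 1.
#' @param nsim Number of replicates the scenario is intended for.
#' @param seed Master seed; each replicate uses a derived substream.
#' @param label Scenario label for reports.
#' @return Object of class `"scenario"` with the resolved `means`.
#' @examples
#' d <- dose_design(c(0, 0.1, 0.4, 1), 100)
#' scenario(d, candidate_model("emax", ed50 = 0.2), effect = 0.4)
#' @export
scenario <- function(design, model = NULL, effect = NULL, means = NULL,
                     sigma = 1, nsim = 10000L, seed = 1L, label = NULL) {
  stopifnot(inherits(design, "dose_design"), sigma > 0, nsim >= 1)
  if (is.null(means)) {
    if (is.null(model) || is.null(effect))
      stop("give either 'means' or both 'model' and 'effect'")
    means <- scaled_profile(model, design, effect)
    if (is.null(label))
      label <- sprintf("%s, effect %g", model$label, effect)
  } else {
    means <- as.numeric(means)
    if (length(means) != length(design$doses) || any(!is.finite(means)))
      stop("'means' must be a finite vector aligned to the design doses")
    if (is.null(label))
      label <- paste0("means (", paste(means, collapse = ", "), ")")
  }
  structure(list(design = design, means = means, sigma = sigma,
                 nsim = as.integer(nsim), seed = as.integer(seed),
                 label = label),
            class = "scenario")
}

#' Simulate one trial replicate
#'
#' Draws per-patient normal responses `Y_ij ~ N(mu_i, sigma^2)` for the
#' scenario's design. Deterministic given the scenario's master seed and the
#' replicate index (independent substreams), and bit-identical on rerun.
#'
#' @param scen A [scenario()].
#' @param replicate Replicate index (>= 1).
#' @return Data frame with columns `dose` and `response`.
#' @export
simulate_trial <- function(scen, replicate = 1L) {
  stopifnot(inherits(scen, "scenario"), replicate >= 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.substream_seed(scen$seed, 0L, replicate))
  d <- scen$design
  data.frame(
    dose = rep(d$doses, d$n),
    response = rep(scen$means, d$n) + stats::rnorm(d$N, 0, scen$sigma)
  )
}

#' Precomputed decision plan for the closed contrast-test procedure
#'
#' Under a fixed design, candidate set and level, the per-intersection
#' contrast matrices, correlation matrices and equicoordinate critical
#' values do not depend on the data. This precomputes them once so that
#' rejection decisions for many simulated trials reduce to comparing each
#' intersection's maximum contrast statistic against its critical value
#' (the exact dual of the adjusted-p-value rule, up to integration
#' tolerance).
#'
#' @param design A [dose_design()].
#' @param models A [candidate_set()].
#' @param constrained Logical; constrained contrasts?
#' @param alpha One-sided level.
#' @param df Degrees of freedom of the pooled variance; defaults to
#'   `N - k - 1` for the design.
#' @return Object of class `"cmcp_plan"`.
#' @seealso [plan_decisions()]
#' @export
closed_mcpmod_plan <- function(design, models, constrained = TRUE,
                               alpha = 0.025,
                               df = design$N - design$k - 1L) {
  stopifnot(inherits(design, "dose_design"), inherits(models, "candidate_set"))
  intersections <- enumerate_intersections(design$k)
  plans <- lapply(intersections, function(I) {
    cmat <- .model_contrast_matrix(design, models, I, constrained)
    R <- contrast_correlation(cmat, design)
    list(I = I,
         cmat = cmat,
         corr = R,
         den = sqrt(drop(crossprod(cmat^2, 1 / design$n))),
         crit = mvt_critical(R, df, alpha))
  })
  member <- vapply(plans, function(p) seq_len(design$k) %in% p$I,
                   logical(design$k))
  member <- matrix(member, nrow = design$k)
  structure(list(design = design, models = models, constrained = constrained,
                 alpha = alpha, df = df, intersections = plans,
                 member = member),
            class = "cmcp_plan")
}

#' Closed-test decisions for (many) trials from a plan
#'
#' @param plan A [closed_mcpmod_plan()].
#' @param means Matrix of arm means, one trial per row (a vector is treated
#'   as a single trial).
#' @param s Vector of pooled standard deviations, one per trial.
#' @return List with logical matrices `intersection` (trials x
#'   intersections: maxT >= critical value) and `elementary` (trials x k:
#'   closure decisions).
#' @export
plan_decisions <- function(plan, means, s) {
  stopifnot(inherits(plan, "cmcp_plan"))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  nrep <- nrow(means)
  stopifnot(length(s) == nrep)
  nI <- length(plan$intersections)
  irej <- matrix(NA, nrep, nI)
  for (j in seq_len(nI)) {
    pj <- plan$intersections[[j]]
    tj <- (means %*% pj$cmat) / (s %o% pj$den)
    irej[, j] <- tj[cbind(seq_len(nrep), max.col(tj, "first"))] >= pj$crit
  }
  erej <- matrix(NA, nrep, plan$design$k)
  for (i in seq_len(plan$design$k))
    erej[, i] <- rowSums(!irej[, plan$member[i, ], drop = FALSE]) == 0L
  list(intersection = irej, elementary = erej)
}

# Step-down Dunnett decisions, vectorized over trials, with the per-subset
# critical values cached (they depend only on the remaining index set).
.stepdown_dunnett_decisions <- function(design, df, alpha, tmat) {
  cache <- new.env(parent = emptyenv())
  crit_for <- function(S) {
    key <- paste(S, collapse = ",")
    if (is.null(cache[[key]]))
      cache[[key]] <- mvt_critical(.dunnett_correlation(design, S), df, alpha)
    cache[[key]]
  }
  k <- design$k
  rej <- matrix(FALSE, nrow(tmat), k)
  for (r in seq_len(nrow(tmat))) {
    ord <- order(tmat[r, ], decreasing = TRUE)
    for (j in seq_len(k)) {
      S <- sort(ord[j:k])
      if (tmat[r, ord[j]] >= crit_for(S)) rej[r, ord[j]] <- TRUE else break
    }
  }
  rej
}

.procedure_labels <- c(
  closed_constrained = "closed MCP-Mod (constrained)",
  closed_unconstrained = "closed MCP-Mod (unconstrained)",
  stepdown_dunnett = "step-down Dunnett",
  hochberg = "Hochberg",
  bonferroni = "Bonferroni",
  fixed_sequence = "fixed sequence",
  unadjusted = "unadjusted t-tests"
)

#' Operating-characteristics study
#'
#' Simulates trials under each scenario and applies each procedure to the
#' *same* replicate data (common random numbers), summarizing the
#' probability of rejecting at least one elementary hypothesis (`RAO`), the
#' per-hypothesis rejection probabilities, and the average number of
#' rejections divided by `k` (`AVE_k`), with binomial Monte-Carlo standard
#' errors.
#'
#' @param scenarios A [scenario()] or list of scenarios (sharing one
#'   design).
#' @param procedures Character subset of `"closed_constrained"`,
#'   `"closed_unconstrained"`, `"stepdown_dunnett"`, `"hochberg"`,
#'   `"bonferroni"`, `"fixed_sequence"`, `"unadjusted"`.
#' @param models A [candidate_set()] for the model-based procedures.
#' @param nsim Replicates per scenario (overrides the scenarios' `nsim`).
#' @param seed Master seed (overrides the scenarios' `seed`); scenario and
#'   replicate indices select independent substreams.
#' @param alpha One-sided significance level.
#' @return Data frame with one row per scenario x procedure: `RAO`, `AVE_k`,
#'   one `pow_H*` column per dose, `se_RAO` and `nsim`. The per-replicate
#'   elementary rejection matrices are attached as attribute `"rejections"`.
#' @export
run_study <- function(scenarios, procedures = c("closed_constrained",
                                                "closed_unconstrained",
                                                "stepdown_dunnett",
                                                "hochberg",
                                                "fixed_sequence"),
                      models = default_candidate_set(),
                      nsim = NULL, seed = NULL, alpha = 0.025) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L)
  procedures <- match.arg(procedures, names(.procedure_labels),
                          several.ok = TRUE)
  design <- scenarios[[1L]]$design
  k <- design$k
  df <- design$N - k - 1L

  plans <- list()
  if ("closed_constrained" %in% procedures)
    plans$closed_constrained <- closed_mcpmod_plan(design, models, TRUE, alpha)
  if ("closed_unconstrained" %in% procedures)
    plans$closed_unconstrained <- closed_mcpmod_plan(design, models, FALSE, alpha)

  out <- list()
  rejections <- list()
  i2 <- seq_len(k) + 1L
  sefac <- sqrt(1 / design$n[i2] + 1 / design$n[1L])
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    if (!identical(scen$design$doses, design$doses))
      stop("all scenarios must share one design")
    ns <- if (is.null(nsim)) scen$nsim else as.integer(nsim)
    if (!is.null(seed)) scen$seed <- .substream_seed(seed, si, 0L)

    means <- matrix(NA_real_, ns, k + 1L)
    s <- numeric(ns)
    for (r in seq_len(ns)) {
      st <- summarize_trial(simulate_trial(scen, r), design)
      means[r, ] <- st$means
      s[r] <- st$s
    }
    tmat <- (means[, i2, drop = FALSE] - means[, 1L]) / (s %o% sefac)
    pmat <- stats::pt(tmat, df = df, lower.tail = FALSE)

    for (proc in procedures) {
      rej <- switch(proc,
        closed_constrained = plan_decisions(plans[[proc]], means, s)$elementary,
        closed_unconstrained = plan_decisions(plans[[proc]], means, s)$elementary,
        stepdown_dunnett = .stepdown_dunnett_decisions(design, df, alpha, tmat),
        hochberg = t(apply(pmat, 1L,
                           function(p) stats::p.adjust(p, "hochberg"))) < alpha,
        bonferroni = t(apply(pmat, 1L,
                             function(p) stats::p.adjust(p, "bonferroni"))) < alpha,
        fixed_sequence = {
          ord <- rev(seq_len(k))
          adj <- t(apply(pmat[, ord, drop = FALSE], 1L, cummax))
          (adj < alpha)[, order(ord), drop = FALSE]
        },
        unadjusted = pmat < alpha
      )
      rao <- mean(rowSums(rej) > 0)
      row <- data.frame(
        scenario = scen$label,
        procedure = proc,
        RAO = rao,
        AVE_k = mean(rowSums(rej)) / k,
        nsim = ns,
        se_RAO = sqrt(rao * (1 - rao) / ns)
      )
      pow <- colMeans(rej)
      for (i in seq_len(k)) row[[paste0("pow_H", i)]] <- pow[i]
      out[[length(out) + 1L]] <- row
      rejections[[paste(scen$label, proc, sep = " | ")]] <- rej
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejections") <- rejections
  res
}
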