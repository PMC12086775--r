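# Graphical extension to a primary and a secondary endpoint: a weighted
# hypothesis graph determines local significance levels for every
# intersection; within an intersection, each endpoint's hypotheses with
# positive level are tested jointly by the constrained model-based contrast
# test at the summed level (Bonferroni split between endpoints).

#' Weighted hypothesis graph
#'
#' Nodes carry initial significance-level weights (fractions of the total
#' level alpha, summing to at most 1); directed edges carry transition
#' weights that redistribute a node's level when it is removed.
#'
#' @param labels Character hypothesis labels.
#' @param weights Nonnegative initial weights (fractions of alpha), summing
#'   to at most 1.
#' @param transitions Square matrix `g` with `g[j, l]` the fraction of
#'   hypothesis `j`'s level passed to `l` upon removal; zero diagonal,
#'   nonnegative entries, row sums at most 1.
#' @param hypotheses Optional data frame (`label`, `endpoint`, `dose`)
#'   mapping each node to an endpoint (1 = primary, 2 = secondary) and an
#'   active-dose index; required for the endpoint-group tests.
#' @return Object of class `"graph_mtp"`.
#' @seealso [two_endpoint_graph()], [local_levels()]
#' @export
graph_mtp <- function(labels, weights, transitions, hypotheses = NULL) {
  labels <- as.character(labels)
  m <- length(labels)
  if (anyDuplicated(labels)) stop("hypothesis labels must be unique")
  weights <- as.numeric(weights)
  if (length(weights) != m || any(weights < -1e-12) ||
      sum(weights) > 1 + 1e-9)
    stop("weights must be nonnegative and sum to at most 1")
  g <- as.matrix(transitions)
  if (!all(dim(g) == m) || any(abs(diag(g)) > 1e-12) || any(g < -1e-12) ||
      any(rowSums(g) > 1 + 1e-9))
    stop("transitions must be square with zero diagonal, nonnegative ",
         "entries and row sums at most 1")
  dimnames(g) <- list(labels, labels)
  names(weights) <- labels
  if (!is.null(hypotheses)) {
    stopifnot(all(c("label", "endpoint", "dose") %in% names(hypotheses)),
              setequal(hypotheses$label, labels))
    hypotheses <- hypotheses[match(labels, hypotheses$label), ]
  }
  structure(list(labels = labels, weights = weights, transitions = g,
                 hypotheses = hypotheses),
            class = "graph_mtp")
}

#' Symmetric primary/secondary two-endpoint graph
#'
#' The default testing strategy for `k` dose-control comparisons on a
#' primary and a secondary endpoint: the total level is split equally among
#' the primary hypotheses (`1/k` each, secondary hypotheses start at 0); on
#' rejection a primary hypothesis passes weight `x` to its own-dose
#' secondary hypothesis and `(1 - x)/(k - 1)` to each other primary
#' hypothesis; a rejected secondary hypothesis passes `1/(k - 1)` to each
#' other dose's primary hypothesis. With the default `x = 1` a secondary
#' hypothesis can only ever receive level through its own-dose primary, so
#' it is testable only after that primary has been rejected.
#'
#' @param k Number of active doses (>= 2 for the cross-dose edges; `k = 1`
#'   gives the hierarchical primary-then-secondary pair).
#' @param x Edge weight from a primary hypothesis to its own-dose secondary,
#'   in `[0, 1]`.
#' @return A [graph_mtp()] with labels `H11..H1k` (primary) and `H21..H2k`
#'   (secondary).
#' @export
two_endpoint_graph <- function(k = 3L, x = 1) {
  k <- as.integer(k)
  stopifnot(k >= 1L, x >= 0, x <= 1)
  labels <- c(paste0("H1", seq_len(k)), paste0("H2", seq_len(k)))
  w <- c(rep(1 / k, k), rep(0, k))
  g <- matrix(0, 2L * k, 2L * k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    g[i, k + i] <- x
    if (k > 1L) {
      g[i, setdiff(seq_len(k), i)] <- (1 - x) / (k - 1L)
      g[k + i, setdiff(seq_len(k), i)] <- 1 / (k - 1L)
    } else {
      g[k + i, i] <- 0  # nowhere to send; weight is lost
    }
  }
  graph_mtp(labels, w, g,
            hypotheses = data.frame(label = labels,
                                    endpoint = rep(1:2, each = k),
                                    dose = rep(seq_len(k), 2L)))
}

#' Local significance levels for an intersection hypothesis
#'
#' Sequentially removes every hypothesis not in the intersection; a removed
#' node's level flows along its outgoing edges
#' (`w_l <- w_l + w_j * g[j, l]`) and the remaining edges are updated as
#' `g[l, m] <- (g[l, m] + g[l, j] * g[j, m]) / (1 - g[l, j] * g[j, l])`
#' (0 when the denominator vanishes). The result does not depend on the
#' removal order.
#'
#' @param graph A [graph_mtp()].
#' @param intersection Character subset of the graph's labels.
#' @param alpha Total significance level; the default 1 returns the levels
#'   as fractions of alpha.
#' @return Named numeric vector of local levels for the hypotheses in the
#'   intersection (summing to at most `alpha`).
#' @examples
#' g <- two_endpoint_graph(3)
#' local_levels(g, c("H11", "H23"), alpha = 0.025)
#' @export
local_levels <- function(graph, intersection, alpha = 1) {
  stopifnot(inherits(graph, "graph_mtp"))
  intersection <- as.character(intersection)
  if (!length(intersection) || !all(intersection %in% graph$labels))
    stop("'intersection' must be a nonempty subset of the graph labels")
  w <- graph$weights
  g <- graph$transitions
  active <- graph$labels
  for (j in setdiff(graph$labels, intersection)) {
    active <- setdiff(active, j)
    w[active] <- w[active] + w[j] * g[j, active]
    w[j] <- 0
    gn <- g
    for (l in active) {
      den <- 1 - g[l, j] * g[j, l]
      for (m in setdiff(active, l)) {
        gn[l, m] <- if (den > 1e-12)
          (g[l, m] + g[l, j] * g[j, m]) / den else 0
      }
    }
    gn[j, ] <- 0
    gn[, j] <- 0
    g <- gn
  }
  alpha * w[graph$labels[graph$labels %in% intersection]]
}

# Constrained model-based group p-value: minimum multivariate-t adjusted
# p-value over the candidate models for the contrast test on the given dose
# subset. Cached by the caller where needed.
.group_pvalue <- function(doses, stats, design, models) {
  cmat <- .model_contrast_matrix(design, models, doses, constrained = TRUE)
  R <- contrast_correlation(cmat, design)
  tstat <- contrast_statistics(stats, cmat)
  min(mvt_pvalues(tstat, R, stats$df))
}

#' Test one intersection of primary and secondary hypotheses
#'
#' Computes the graph's local levels for the intersection, splits the level
#' between the endpoint groups (Bonferroni), and tests each endpoint's
#' positive-level hypotheses jointly with the constrained model-based
#' contrast test on their doses at the group's summed level. The
#' intersection is rejected if either group test is significant; a group
#' with summed level 0 is never significant.
#'
#' @param intersection Character subset of the graph's labels.
#' @param stats_primary,stats_secondary `"summary_stats"` for the two
#'   endpoints (same design).
#' @param design A [dose_design()].
#' @param models A [candidate_set()] shared by both endpoints.
#' @param graph A [graph_mtp()] with an endpoint/dose mapping.
#' @param alpha Total one-sided level.
#' @return List with `levels`, per-group summed levels and p-values,
#'   `p_value` (weighted-Bonferroni intersection p-value) and `reject`.
#' @export
test_intersection_graphical <- function(intersection, stats_primary,
                                        stats_secondary, design, models,
                                        graph, alpha = 0.025) {
  stopifnot(inherits(graph, "graph_mtp"), !is.null(graph$hypotheses))
  lev <- local_levels(graph, intersection, alpha)
  hyp <- graph$hypotheses
  stats_by_ep <- list(stats_primary, stats_secondary)
  groups <- list()
  p_I <- Inf
  reject <- FALSE
  for (ep in 1:2) {
    members <- intersection[hyp$endpoint[match(intersection, hyp$label)] == ep &
                            lev[intersection] > 1e-15]
    L <- sum(lev[members])
    pg <- NA_real_
    if (length(members) && L > 0) {
      doses <- sort(hyp$dose[match(members, hyp$label)])
      pg <- .group_pvalue(doses, stats_by_ep[[ep]], design, models)
      p_I <- min(p_I, pg * alpha / L)
      if (pg < L) reject <- TRUE
    }
    groups[[ep]] <- list(members = members, level = L, p = pg)
  }
  list(levels = lev, groups = groups,
       p_value = min(1, p_I), reject = reject, alpha = alpha)
}

#' Closed testing over a primary and a secondary endpoint
#'
#' Exhaustive closure over all `2^(2k) - 1` intersections of the `2k`
#' primary and secondary dose-control hypotheses, each tested by
#' [test_intersection_graphical()]. With the default graph the zero initial
#' secondary levels make a secondary hypothesis rejectable only after its
#' own-dose primary hypothesis: the successiveness restriction emerges from
#' the graph rather than being hard-coded. The procedure controls the
#' familywise error rate strongly across both endpoints.
#'
#' @param data_primary,data_secondary Data frames (`dose`, `response`) or
#'   `"summary_stats"`, one per endpoint, on the same design.
#' @param design A [dose_design()].
#' @param models A [candidate_set()] shared by both endpoints.
#' @param graph A [graph_mtp()]; defaults to [two_endpoint_graph()] for the
#'   design's `k`.
#' @param alpha Total one-sided familywise level.
#' @return Object of class `"closed_graphical"`: `elementary` data frame
#'   (label, endpoint, dose, closed-test adjusted p, reject), the
#'   per-intersection results, and the inputs.
#' @export
closed_graphical_mcpmod <- function(data_primary, data_secondary, design,
                                    models, graph = NULL, alpha = 0.025) {
  stopifnot(inherits(design, "dose_design"), inherits(models, "candidate_set"))
  if (is.null(graph)) graph <- two_endpoint_graph(design$k)
  stopifnot(inherits(graph, "graph_mtp"), !is.null(graph$hypotheses))
  st1 <- if (inherits(data_primary, "summary_stats")) data_primary
         else summarize_trial(data_primary, design)
  st2 <- if (inherits(data_secondary, "summary_stats")) data_secondary
         else summarize_trial(data_secondary, design)
  labels <- graph$labels
  m <- length(labels)
  if (m > 16L) stop("exhaustive closure limited to 2k <= 16 hypotheses")

  # cache the endpoint-group p-values: they depend only on (endpoint, doses)
  cache <- new.env(parent = emptyenv())
  hyp <- graph$hypotheses
  stats_by_ep <- list(st1, st2)
  group_p <- function(ep, doses) {
    key <- paste(ep, paste(doses, collapse = ","))
    if (is.null(cache[[key]]))
      cache[[key]] <- .group_pvalue(doses, stats_by_ep[[ep]], design, models)
    cache[[key]]
  }

  nI <- 2L^m - 1L
  p_I <- numeric(nI)
  member <- matrix(FALSE, nI, m, dimnames = list(NULL, labels))
  for (b in seq_len(nI)) {
    inI <- as.logical(bitwAnd(b, 2L^(seq_len(m) - 1L)))
    member[b, ] <- inI
    I <- labels[inI]
    lev <- local_levels(graph, I, alpha)
    p <- Inf
    for (ep in 1:2) {
      mem <- I[hyp$endpoint[match(I, hyp$label)] == ep & lev[I] > 1e-15]
      L <- sum(lev[mem])
      if (length(mem) && L > 0) {
        doses <- sort(hyp$dose[match(mem, hyp$label)])
        p <- min(p, group_p(ep, doses) * alpha / L)
      }
    }
    p_I[b] <- min(1, p)
  }
  adj <- vapply(seq_len(m), function(j) max(p_I[member[, j]]), numeric(1))
  elementary <- data.frame(
    hypothesis = labels,
    endpoint = hyp$endpoint,
    dose = design$doses[hyp$dose + 1L],
    adjusted_p = adj,
    reject = adj < alpha
  )
  structure(list(elementary = elementary, intersection_p = p_I,
                 member = member, alpha = alpha, graph = graph,
                 design = design, models = models),
            class = "closed_graphical")
}

#' @export
print.closed_graphical <- function(x, digits = 4, ...) {
  cat("Closed two-endpoint model-based contrast test (alpha =", x$alpha,
      ")\n")
  el <- x$elementary
  el$adjusted_p <- round(el$adjusted_p, digits)
  print(el, row.names = FALSE)
  invisible(x)
}

#' Decision plan for two-endpoint closed testing
#'
#' Precomputes, for every intersection, the endpoint groups' contrast
#' matrices and equicoordinate critical values at their local levels so that
#' simulated two-endpoint trials can be tested by pure arithmetic.
#'
#' @inheritParams closed_graphical_mcpmod
#' @param df Pooled-variance degrees of freedom (default `N - k - 1`).
#' @return Object of class `"graphical_plan"` for [graphical_decisions()].
#' @export
closed_graphical_plan <- function(design, models, graph = NULL,
                                  alpha = 0.025,
                                  df = design$N - design$k - 1L) {
  stopifnot(inherits(design, "dose_design"))
  if (is.null(graph)) graph <- two_endpoint_graph(design$k)
  stopifnot(inherits(graph, "graph_mtp"), !is.null(graph$hypotheses))
  labels <- graph$labels
  m <- length(labels)
  hyp <- graph$hypotheses
  ccache <- new.env(parent = emptyenv())
  gcache <- new.env(parent = emptyenv())
  contrasts_for <- function(doses) {
    key <- paste(doses, collapse = ",")
    if (is.null(ccache[[key]])) {
      cmat <- .model_contrast_matrix(design, models, doses, constrained = TRUE)
      ccache[[key]] <- list(
        cmat = cmat,
        corr = contrast_correlation(cmat, design),
        den = sqrt(drop(crossprod(cmat^2, 1 / design$n))))
    }
    ccache[[key]]
  }
  crit_for <- function(doses, level) {
    key <- paste(paste(doses, collapse = ","), signif(level, 12))
    if (is.null(gcache[[key]]))
      gcache[[key]] <- mvt_critical(contrasts_for(doses)$corr, df, level)
    gcache[[key]]
  }
  nI <- 2L^m - 1L
  member <- matrix(FALSE, nI, m, dimnames = list(NULL, labels))
  tests <- vector("list", nI)
  for (b in seq_len(nI)) {
    inI <- as.logical(bitwAnd(b, 2L^(seq_len(m) - 1L)))
    member[b, ] <- inI
    I <- labels[inI]
    lev <- local_levels(graph, I, alpha)
    gr <- list()
    for (ep in 1:2) {
      mem <- I[hyp$endpoint[match(I, hyp$label)] == ep & lev[I] > 1e-15]
      L <- sum(lev[mem])
      if (length(mem) && L > 0) {
        doses <- sort(hyp$dose[match(mem, hyp$label)])
        cf <- contrasts_for(doses)
        gr[[length(gr) + 1L]] <- list(endpoint = ep, cmat = cf$cmat,
                                      den = cf$den,
                                      crit = crit_for(doses, L))
      }
    }
    tests[[b]] <- gr
  }
  structure(list(design = design, graph = graph, alpha = alpha, df = df,
                 member = member, tests = tests),
            class = "graphical_plan")
}

#' Closed-test decisions for simulated two-endpoint trials
#'
#' @param plan A [closed_graphical_plan()].
#' @param means1,means2 Matrices of arm means per endpoint (trials in rows).
#' @param s1,s2 Pooled standard deviations per endpoint (one per trial).
#' @return Logical matrix (trials x hypotheses, columns in graph label
#'   order) of closed-test rejections.
#' @export
graphical_decisions <- function(plan, means1, s1, means2, s2) {
  stopifnot(inherits(plan, "graphical_plan"))
  if (is.null(dim(means1))) means1 <- matrix(means1, nrow = 1L)
  if (is.null(dim(means2))) means2 <- matrix(means2, nrow = 1L)
  nrep <- nrow(means1)
  mlist <- list(means1, means2)
  slist <- list(s1, s2)
  nI <- nrow(plan$member)
  irej <- matrix(FALSE, nrep, nI)
  for (b in seq_len(nI)) {
    for (g in plan$tests[[b]]) {
      tg <- (mlist[[g$endpoint]] %*% g$cmat) / (slist[[g$endpoint]] %o% g$den)
      tmax <- tg[cbind(seq_len(nrep), max.col(tg, "first"))]
      irej[, b] <- irej[, b] | (tmax >= g$crit)
    }
  }
  m <- ncol(plan$member)
  erej <- matrix(FALSE, nrep, m, dimnames = list(NULL, colnames(plan$member)))
  for (j in seq_len(m))
    erej[, j] <- rowSums(!irej[, plan$member[, j], drop = FALSE]) == 0L
  erej
}
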