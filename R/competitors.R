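# Reference many-to-one procedures: unadjusted one-sided t tests,
# Bonferroni, Hochberg, single-step and step-down Dunnett, fixed sequence.

.adjp <- function(procedure, hypothesis, p, adjusted, alpha) {
  structure(data.frame(hypothesis = hypothesis, p = p,
                       adjusted_p = pmin(adjusted, 1),
                       reject = pmin(adjusted, 1) < alpha),
            procedure = procedure, alpha = alpha,
            class = c("adjusted_pvalues", "data.frame"))
}

#' Unadjusted one-sided pairwise t-test p-values
#'
#' One p-value per active dose for the comparison against control, using the
#' pooled standard deviation over all arms and `N - k - 1` degrees of
#' freedom: `T_i = (mean_i - mean_0) / (S * sqrt(1/n_i + 1/n_0))`.
#'
#' @param stats A `"summary_stats"` object from [summarize_trial()].
#' @param design A [dose_design()].
#' @return Numeric vector of `k` one-sided p-values (small when the dose
#'   beats control).
#' @export
pairwise_t_pvalues <- function(stats, design) {
  stopifnot(inherits(stats, "summary_stats"), inherits(design, "dose_design"))
  i <- seq_len(design$k) + 1L
  t <- (stats$means[i] - stats$means[1L]) /
    (stats$s * sqrt(1 / stats$n[i] + 1 / stats$n[1L]))
  stats::pt(t, df = stats$df, lower.tail = FALSE)
}

#' Bonferroni and Hochberg adjustments
#'
#' Thin wrappers around [stats::p.adjust()] returning the package's
#' adjusted-p-value container with rejection flags.
#'
#' @param p Vector of unadjusted p-values, one per elementary hypothesis.
#' @param alpha Significance level for the rejection flags.
#' @return An `"adjusted_pvalues"` data frame (hypothesis, p, adjusted_p,
#'   reject).
#' @export
bonferroni <- function(p, alpha = 0.025) {
  .adjp("bonferroni", paste0("H", seq_along(p)), p,
        stats::p.adjust(p, "bonferroni"), alpha)
}

#' @rdname bonferroni
#' @export
hochberg <- function(p, alpha = 0.025) {
  .adjp("hochberg", paste0("H", seq_along(p)), p,
        stats::p.adjust(p, "hochberg"), alpha)
}

# Many-to-one correlation of the pairwise t statistics for a subset of
# active doses: rho_ij = sqrt(n_i n_j / ((n0 + n_i)(n0 + n_j))).
.dunnett_correlation <- function(design, subset = seq_len(design$k)) {
  n0 <- design$n[1L]
  ni <- design$n[subset + 1L]
  lam <- sqrt(ni / (n0 + ni))
  R <- tcrossprod(lam)
  diag(R) <- 1
  R
}

#' Single-step Dunnett test
#'
#' Many-to-one comparisons adjusted through the joint multivariate t
#' distribution of all `k` pairwise statistics.
#'
#' @inheritParams pairwise_t_pvalues
#' @param alpha One-sided significance level.
#' @return An `"adjusted_pvalues"` data frame.
#' @export
dunnett_test <- function(stats, design, alpha = 0.025) {
  p <- pairwise_t_pvalues(stats, design)
  t <- stats::qt(p, df = stats$df, lower.tail = FALSE)
  R <- .dunnett_correlation(design)
  adj <- as.numeric(mvt_pvalues(t, R, stats$df))
  .adjp("dunnett", paste0("H", seq_along(p)), p, adj, alpha)
}

#' Step-down Dunnett test
#'
#' The closed Dunnett test via its shortcut: order statistics are compared
#' against shrinking equicoordinate multivariate-t critical values over the
#' not-yet-rejected comparisons; adjusted p-values are monotonicity-enforced
#' (each step's p is at least the previous step's).
#'
#' @inheritParams dunnett_test
#' @return An `"adjusted_pvalues"` data frame in the original hypothesis
#'   order.
#' @export
stepdown_dunnett <- function(stats, design, alpha = 0.025) {
  p <- pairwise_t_pvalues(stats, design)
  t <- stats::qt(p, df = stats$df, lower.tail = FALSE)
  ord <- order(t, decreasing = TRUE)
  k <- length(t)
  adj <- numeric(k)
  run <- 0
  for (j in seq_len(k)) {
    S <- sort(ord[j:k])
    R <- .dunnett_correlation(design, S)
    qj <- as.numeric(mvt_pvalues(rep(t[ord[j]], length(S)), R, stats$df)[1L])
    run <- max(run, qj)
    adj[ord[j]] <- run
  }
  .adjp("stepdown_dunnett", paste0("H", seq_len(k)), p, adj, alpha)
}

#' Fixed-sequence test
#'
#' Hypotheses are tested in a pre-specified order (by default highest dose
#' first) each at the unadjusted level; testing stops at the first failure.
#' The sequential adjusted p-value is the running maximum along the
#' sequence.
#'
#' @param p Unadjusted p-values in hypothesis order `H1..Hk` (lowest dose
#'   first).
#' @param alpha Significance level.
#' @param order Testing order as indices into `p`; defaults to
#'   `length(p):1` (highest dose first).
#' @return An `"adjusted_pvalues"` data frame in the original order.
#' @export
fixed_sequence <- function(p, alpha = 0.025, order = rev(seq_along(p))) {
  stopifnot(setequal(order, seq_along(p)))
  adj <- numeric(length(p))
  adj[order] <- cummax(p[order])
  .adjp("fixed_sequence", paste0("H", seq_along(p)), p, adj, alpha)
}

#' @export
print.adjusted_pvalues <- function(x, digits = 4, ...) {
  cat("Procedure:", attr(x, "procedure"),
      "(alpha =", attr(x, "alpha"), ")\n")
  y <- as.data.frame(x)
  y$p <- round(y$p, digits)
  y$adjusted_p <- round(y$adjusted_p, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
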