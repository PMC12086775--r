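# Contrast test statistics, pooled variance, and multivariate-t
# multiplicity adjustment (adjusted p-values and equicoordinate critical
# values via randomized quasi-Monte-Carlo integration, mvtnorm).

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# Keeps the Genz-Bretz randomized integration reproducible without
# interfering with user-level simulation streams.
.with_mvt_seed <- function(expr, seed = getOption("cmcpmod.mvt.seed", 20260920L)) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.mvt_algorithm <- function() {
  mvtnorm::GenzBretz(maxpts = 50000L, abseps = 5e-5)
}

.check_corr <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || any(abs(R - t(R)) > 1e-8) ||
      any(abs(diag(R) - 1) > 1e-8) || any(R < -1 - 1e-8) || any(R > 1 + 1e-8))
    stop("invalid correlation matrix")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) stop("correlation matrix is not positive semidefinite")
  R
}

#' Per-arm summary statistics with pooled variance
#'
#' Computes arm means and the pooled variance over all `k + 1` arms with
#' `N - k - 1` degrees of freedom. The pooled variance is always taken over
#' every arm of the design, including when later tests restrict attention to
#' a subset of doses.
#'
#' @param data Data frame with columns `dose` and `response`; every design
#'   dose must appear with at least 2 observations, and dose values must
#'   match the design grid exactly.
#' @param design A [dose_design()].
#' @return An object of class `"summary_stats"`: list with `means`, `s2`
#'   (pooled variance), `s` (its square root), `df`, `n` and `design`.
#' @examples
#' d <- dose_design(c(0, 1), c(2, 2))
#' summarize_trial(data.frame(dose = c(0, 0, 1, 1),
#'                            response = c(0, 2, 1, 3)), d)
#' @export
summarize_trial <- function(data, design) {
  stopifnot(inherits(design, "dose_design"))
  if (!is.data.frame(data) || !all(c("dose", "response") %in% names(data)))
    stop("'data' must have columns 'dose' and 'response'")
  arm <- match(as.numeric(data$dose), design$doses)
  if (anyNA(arm))
    stop("doses not in the design grid: ",
         paste(unique(data$dose[is.na(arm)]), collapse = ", "))
  if (any(!is.finite(data$response))) stop("responses must be finite")
  nobs <- tabulate(arm, nbins = length(design$doses))
  if (any(nobs < 2L))
    stop("every arm needs at least 2 observations; short arms at dose(s): ",
         paste(design$doses[nobs < 2L], collapse = ", "))
  means <- as.numeric(rowsum(data$response, arm) / nobs)
  ss <- as.numeric(rowsum(data$response^2, arm)) - nobs * means^2
  df <- sum(nobs) - length(nobs)
  s2 <- sum(ss) / df
  if (s2 <= 0) stop("pooled variance is zero; responses are constant per arm")
  structure(list(means = means, s2 = s2, s = sqrt(s2), df = df,
                 n = nobs, design = design),
            class = "summary_stats")
}

# Summary stats assembled directly from arm-level quantities (simulation
# fast path and tests).
summary_stats <- function(means, s2, df, design) {
  stopifnot(inherits(design, "dose_design"), s2 > 0, df >= 1)
  structure(list(means = as.numeric(means), s2 = s2, s = sqrt(s2),
                 df = as.integer(df), n = design$n, design = design),
            class = "summary_stats")
}

#' Contrast test statistics
#'
#' Computes `T_m = sum(c_m * means) / (S * sqrt(sum(c_m^2 / n)))` for each
#' contrast column, with `S` the pooled standard deviation over all arms.
#'
#' @param stats A `"summary_stats"` object from [summarize_trial()].
#' @param cmat Contrast matrix (one contrast per column) aligned to the
#'   design arms, or a single contrast vector.
#' @return Named numeric vector of t statistics.
#' @export
contrast_statistics <- function(stats, cmat) {
  stopifnot(inherits(stats, "summary_stats"))
  cmat <- as.matrix(cmat)
  if (nrow(cmat) != length(stats$means))
    stop("contrast rows must align to the design arms")
  num <- drop(crossprod(cmat, stats$means))
  den <- stats$s * sqrt(drop(crossprod(cmat^2, 1 / stats$n)))
  num / den
}

#' Multiplicity-adjusted p-values from the multivariate t distribution
#'
#' For statistics `t_m` that are jointly central multivariate t under the
#' null with correlation `R` and `df` degrees of freedom, the one-sided
#' maxT-adjusted p-value of statistic `t_m` is
#' `q_m = 1 - P(T_1 <= t_m, ..., T_M <= t_m)`. Probabilities are computed by
#' randomized quasi-Monte-Carlo integration (Genz-Bretz) under a fixed
#' internal seed (option `cmcpmod.mvt.seed`), so results are reproducible;
#' the largest reported integration error is attached as attribute
#' `"error"`. Numerically identical statistics/contrasts (correlation 1) are
#' deduplicated before integration.
#'
#' @param statistics Numeric vector of t statistics.
#' @param corr Correlation matrix of the statistics.
#' @param df Degrees of freedom (`N - k - 1`).
#' @return Numeric vector of adjusted p-values in `[0, 1]`.
#' @examples
#' R <- diag(2)
#' mvt_pvalues(c(2, 2), R, df = 10000)  # close to 1 - pnorm(2)^2
#' @export
mvt_pvalues <- function(statistics, corr, df) {
  statistics <- as.numeric(statistics)
  corr <- .check_corr(corr)
  if (length(statistics) != nrow(corr))
    stop("length of statistics must match the correlation dimension")
  if (df < 1) stop("df must be >= 1")
  if (length(statistics) == 1L) {
    q <- stats::pt(statistics, df = df, lower.tail = FALSE)
    attr(q, "error") <- 0
    return(q)
  }
  # collapse perfectly correlated coordinates
  u <- .corr_groups(corr)$keep
  Ru <- corr[u, u, drop = FALSE]
  q <- numeric(length(statistics))
  err <- 0
  for (i in seq_along(statistics)) {
    if (length(u) == 1L) {
      q[i] <- stats::pt(statistics[i], df = df, lower.tail = FALSE)
    } else {
      pr <- .with_mvt_seed(
        mvtnorm::pmvt(lower = rep(-Inf, length(u)),
                      upper = rep(statistics[i], length(u)),
                      df = as.integer(df), corr = Ru,
                      algorithm = .mvt_algorithm())
      )
      err <- max(err, attr(pr, "error"))
      q[i] <- 1 - as.numeric(pr)
    }
  }
  q <- pmin(pmax(q, 0), 1)
  names(q) <- names(statistics)
  attr(q, "error") <- err
  q
}

# Group coordinates whose pairwise correlation is 1 (within 1e-12): returns
# representative indices.
.corr_groups <- function(R, tol = 1e-12) {
  m <- nrow(R)
  keep <- integer(0)
  for (j in seq_len(m)) {
    dup <- FALSE
    for (i in keep) if (R[i, j] >= 1 - tol) { dup <- TRUE; break }
    if (!dup) keep <- c(keep, j)
  }
  list(keep = keep)
}

#' Equicoordinate multivariate-t critical value
#'
#' The one-sided critical value `c` with
#' `P(T_1 <= c, ..., T_M <= c) = 1 - alpha` under the central multivariate t
#' distribution; the maxT test rejects when `max(T_m) >= c`. Consistent by
#' construction with [mvt_pvalues()] (duality up to integration error).
#'
#' @param corr Correlation matrix.
#' @param df Degrees of freedom.
#' @param alpha One-sided significance level in `(0, 1)`.
#' @return Scalar critical value.
#' @export
mvt_critical <- function(corr, df, alpha = 0.025) {
  corr <- .check_corr(corr)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  u <- .corr_groups(corr)$keep
  if (length(u) == 1L)
    return(stats::qt(1 - alpha, df = df))
  Ru <- corr[u, u, drop = FALSE]
  M <- length(u)
  # exact bracket: univariate quantile below, Bonferroni quantile above
  lo <- stats::qt(1 - alpha, df = df)
  hi <- stats::qt(1 - alpha / M, df = df)
  f <- function(cc) {
    pr <- .with_mvt_seed(
      mvtnorm::pmvt(lower = rep(-Inf, M), upper = rep(cc, M),
                    df = as.integer(df), corr = Ru,
                    algorithm = .mvt_algorithm()))
    as.numeric(pr) - (1 - alpha)
  }
  stats::uniroot(f, lower = lo - 1e-8, upper = hi + 1e-8,
                 extendInt = "upX", tol = 1e-6)$root
}
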