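# Contrast optimizers: unconstrained (maximum noncentrality) and
# nonnegativity-constrained coefficients, per candidate model and
# intersection index set, plus the contrast-test correlation matrix.

.check_subset <- function(subset, k) {
  subset <- sort(unique(as.integer(subset)))
  if (!length(subset) || any(subset < 1L) || any(subset > k))
    stop("'subset' must be a nonempty set of active-dose indices in 1..k")
  subset
}

.precision_matrix <- function(design, precision = NULL) {
  if (is.null(precision)) return(diag(1 / design$n))
  A <- as.matrix(precision)
  p <- length(design$doses)
  if (!all(dim(A) == p)) stop("precision matrix dimensions must match design")
  if (any(abs(A - t(A)) > 1e-8)) stop("precision matrix must be symmetric")
  if (any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("precision matrix must be positive definite")
  A
}

# Core solver: maximize (c'mu) / sqrt(c'Ac) subject to sum(c) = 0 over the
# arms in J (1-based positions, control included); coefficients outside J
# are exactly zero. Returns the unit-norm vector oriented so c'mu > 0.
.opt_contrast_core <- function(mu, A, J, p) {
  muJ <- mu[J]
  AJ <- A[J, J, drop = FALSE]
  Ainv <- solve(AJ)
  one <- rep(1, length(J))
  mubar <- drop(crossprod(one, Ainv %*% muJ)) / drop(crossprod(one, Ainv %*% one))
  cj <- drop(Ainv %*% (muJ - mubar))
  nrm <- sqrt(sum(cj^2))
  if (nrm <= 1e-12 * max(1, max(abs(muJ)))) return(NULL)
  cj <- cj / nrm
  if (sum(cj * muJ) < 0) cj <- -cj
  cc <- numeric(p)
  cc[J] <- cj
  cc
}

#' Optimal contrast coefficients for a mean profile
#'
#' Computes the unit-norm, zero-sum contrast vector that maximizes the
#' noncentrality parameter `c'mu / sqrt(c'Ac)` for an assumed mean profile
#' `mu`, over the control arm plus the active doses in `subset`; all other
#' coefficients are exactly 0. With the default precision `A = diag(1/n)`
#' the solution has coefficients proportional to `n_i * (mu_i - mubar)` with
#' `mubar` the allocation-weighted profile mean over the used arms.
#'
#' @param profile Numeric mean profile aligned to `design$doses` (for example
#'   from [scaled_profile()] or [std_response()]; any affine transform gives
#'   the same contrast).
#' @param design A [dose_design()].
#' @param subset Active-dose indices (in `1..k`) used by the contrast;
#'   defaults to all active doses.
#' @param precision Optional symmetric positive-definite matrix `A`,
#'   proportional to the covariance of the arm mean estimates; defaults to
#'   `diag(1/n)`.
#' @return Numeric contrast vector of length `k + 1` with `sum(c) = 0`,
#'   `sum(c^2) = 1`, oriented so that `sum(c * profile) > 0`.
#' @examples
#' d <- dose_design(c(0, 0.1, 0.4, 1), 100)
#' mu <- std_response(candidate_model("emax", ed50 = 0.05), d$doses)
#' round(optimal_contrast(mu, d), 3)
#' @export
optimal_contrast <- function(profile, design, subset = seq_len(design$k),
                             precision = NULL) {
  stopifnot(inherits(design, "dose_design"))
  p <- length(design$doses)
  profile <- as.numeric(profile)
  if (length(profile) != p || any(!is.finite(profile)))
    stop("'profile' must be a finite vector aligned to the design doses")
  subset <- .check_subset(subset, design$k)
  A <- .precision_matrix(design, precision)
  cc <- .opt_contrast_core(profile, A, c(1L, subset + 1L), p)
  if (is.null(cc))
    stop("profile is constant over the selected arms; contrast is degenerate")
  names(cc) <- format(design$doses)
  cc
}

#' Nonnegativity-constrained optimal contrast
#'
#' Maximizes the same noncentrality objective as [optimal_contrast()] under
#' the additional constraint that every active-dose coefficient is
#' nonnegative (equivalently, placebo-difference weights `w >= 0`), which
#' yields a genuinely one-sided dose-versus-control test: a negative
#' coefficient on an active dose can never contribute evidence.
#'
#' The solver enumerates every nonempty support `S` within `subset`, solves
#' the unconstrained problem on `{control} + S`, discards solutions with a
#' negative dose coefficient (tolerance `-1e-12`), and returns the feasible
#' maximizer of the objective. Singleton supports are always feasible, so a
#' solution always exists; the enumeration is exact (KKT-consistent) and
#' intended for `k <= 15`.
#'
#' @inheritParams optimal_contrast
#' @return Unit-norm, zero-sum contrast with all active-dose coefficients
#'   `>= 0`.
#' @examples
#' d <- dose_design(c(0, 0.1, 0.4, 1), 100)
#' mu <- std_response(candidate_model("sigEmax", ed50 = 0.6, h = 2), d$doses)
#' round(constrained_contrast(mu, d), 3)  # collapses to the top dose
#' @export
constrained_contrast <- function(profile, design, subset = seq_len(design$k),
                                 precision = NULL) {
  stopifnot(inherits(design, "dose_design"))
  p <- length(design$doses)
  profile <- as.numeric(profile)
  if (length(profile) != p || any(!is.finite(profile)))
    stop("'profile' must be a finite vector aligned to the design doses")
  subset <- .check_subset(subset, design$k)
  if (length(subset) > 15L) stop("support enumeration limited to k <= 15")
  A <- .precision_matrix(design, precision)
  best <- NULL
  best_obj <- -Inf
  ns <- length(subset)
  for (code in seq_len(2L^ns - 1L)) {
    S <- subset[as.logical(bitwAnd(code, 2L^(seq_len(ns) - 1L)))]
    cc <- .opt_contrast_core(profile, A, c(1L, S + 1L), p)
    if (is.null(cc)) next
    if (any(cc[S + 1L] < -1e-12)) next
    obj <- sum(cc * profile) / sqrt(drop(crossprod(cc, A %*% cc)))
    if (obj > best_obj) {
      best_obj <- obj
      best <- cc
    }
  }
  if (is.null(best)) {
    # no dose improves on control: every oriented support is infeasible and
    # the constrained optimum sits on a singleton with forced positive dose
    # weight (objective <= 0); pick the least unfavorable comparison
    if (.profile_degenerate(profile[c(1L, subset + 1L)]))
      stop("profile is constant over the selected arms; contrast is degenerate")
    obj1 <- vapply(subset, function(i) {
      cc <- numeric(p); cc[i + 1L] <- 1; cc[1L] <- -1
      sum(cc * profile) / sqrt(drop(crossprod(cc, A %*% cc)))
    }, numeric(1))
    i <- subset[which.max(obj1)]
    best <- numeric(p)
    best[c(1L, i + 1L)] <- c(-1, 1) / sqrt(2)
  }
  best[abs(best) < 1e-15] <- 0
  names(best) <- format(design$doses)
  best
}

#' Correlation matrix of contrast test statistics
#'
#' For contrasts `c_m` (columns of `cmat`) applied to independent arm means
#' with variances proportional to `1/n_i`, the test statistics are jointly
#' multivariate t with correlation
#' `R[m, m'] = sum(c_m c_m' / n) / sqrt(sum(c_m^2/n) sum(c_m'^2/n))`.
#'
#' @param cmat Matrix with one contrast per column, rows aligned to
#'   `design$doses`.
#' @param design A [dose_design()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
contrast_correlation <- function(cmat, design) {
  stopifnot(inherits(design, "dose_design"))
  cmat <- as.matrix(cmat)
  if (nrow(cmat) != length(design$doses))
    stop("contrast rows must align to the design doses")
  v <- crossprod(cmat, cmat / design$n)
  d <- sqrt(diag(v))
  if (any(d <= 0)) stop("zero contrast supplied")
  R <- v / tcrossprod(d)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  dimnames(R) <- list(colnames(cmat), colnames(cmat))
  R
}

# Contrast matrix (arms x models) for one intersection; degenerate models
# are dropped with a warning (attribute "dropped" lists their labels).
.model_contrast_matrix <- function(design, models, subset, constrained,
                                   precision = NULL) {
  fun <- if (constrained) constrained_contrast else optimal_contrast
  cols <- list()
  dropped <- character(0)
  for (lab in names(models)) {
    mu <- std_response(models[[lab]], design$doses)
    cc <- tryCatch(fun(mu, design, subset, precision), error = function(e) NULL)
    if (is.null(cc)) dropped <- c(dropped, lab) else cols[[lab]] <- cc
  }
  if (!length(cols))
    stop("all candidate models are degenerate on this intersection")
  if (length(dropped))
    warning("dropped degenerate model(s) on this intersection: ",
            paste(dropped, collapse = ", "))
  cmat <- do.call(cbind, cols)
  attr(cmat, "dropped") <- dropped
  cmat
}

#' Contrast table over all intersection hypotheses
#'
#' Computes the per-model optimal (or constrained) contrasts for every
#' nonempty intersection of the elementary dose-versus-control hypotheses,
#' the closed-test analogue of the single global contrast set.
#'
#' @param design A [dose_design()].
#' @param models A [candidate_set()].
#' @param constrained Logical; use the nonnegativity-constrained solver?
#' @return A data frame with one row per intersection and model: columns
#'   `hypothesis` (e.g. `"H{1,2,3}"`), `model`, and one coefficient column
#'   per arm.
#' @examples
#' tab <- contrast_table(dose_design(c(0, 0.1, 0.4, 1), 100),
#'                       default_candidate_set())
#' head(tab)
#' @export
contrast_table <- function(design, models, constrained = FALSE) {
  stopifnot(inherits(models, "candidate_set"))
  rows <- list()
  for (I in enumerate_intersections(design$k)) {
    cmat <- .model_contrast_matrix(design, models, I, constrained)
    for (lab in colnames(cmat)) {
      co <- as.list(round(cmat[, lab], 6))
      names(co) <- paste0("d", design$doses)
      rows[[length(rows) + 1L]] <- c(
        list(hypothesis = paste0("H{", paste(I, collapse = ","), "}"),
             model = lab), co)
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
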