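# Shared fixtures and independent numeric oracles used across the suite.

case_design <- function(n = 100L) dose_design(c(0, 0.1, 0.4, 1), n)

# random design with k active doses and unequal allocations
random_design <- function(k) {
  dose_design(c(0, sort(stats::runif(k, 0.05, 1))),
              sample(50:150, k + 1L, replace = TRUE))
}

# random mean profile with at least one dose above control
random_profile <- function(k) {
  mu <- cumsum(stats::runif(k + 1L, -0.3, 0.6))
  if (all(mu[-1L] <= mu[1L])) mu <- mu - 2 * (mu - mu[1L])
  mu
}

# noncentrality objective of a contrast for a profile under diag(1/n)
contrast_objective <- function(cc, mu, n) {
  sum(cc * mu) / sqrt(sum(cc^2 / n))
}

# Unconstrained oracle: numerical maximization of the noncentrality over the
# zero-sum unit sphere restricted to arms J (1-based, control included).
oracle_optimal <- function(mu, n, J, starts = 5L) {
  p <- length(mu)
  obj <- function(z) {
    cc <- numeric(p)
    cc[J] <- z - mean(z)
    den <- sqrt(sum(cc^2 / n))
    if (den < 1e-14) return(1e6)
    -sum(cc * mu) / den
  }
  best <- Inf
  bz <- NULL
  for (s in seq_len(starts)) {
    z0 <- stats::rnorm(length(J))
    o <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (o$value < best) { best <- o$value; bz <- o$par }
  }
  cc <- numeric(p)
  cc[J] <- bz - mean(bz)
  cc <- cc / sqrt(sum(cc^2))
  if (sum(cc * mu) < 0) cc <- -cc
  cc
}

# Constrained oracle: smooth w = z^2 reparameterization of the nonnegative
# weight problem, multi-start BFGS + Nelder-Mead polish; returns the best
# objective value found.
oracle_constrained_objective <- function(mu, n, I, starts = 8L) {
  p <- length(mu)
  obj <- function(z) {
    w <- z^2
    cc <- numeric(p)
    cc[I + 1L] <- w
    cc[1L] <- -sum(w)
    den <- sqrt(sum(cc^2 / n))
    if (den < 1e-14) return(1e6)
    -sum(cc * mu) / den
  }
  best <- Inf
  for (s in seq_len(starts)) {
    z0 <- if (s == 1L) rep(1, length(I)) else stats::rnorm(length(I))
    o <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-16))
    if (o$value < best) best <- o$value
  }
  -best
}

# Straight-line reimplementation of the whole closed procedure, written
# independently of the package internals (plain formulas, explicit loops).
oracle_closed <- function(data, design, models, constrained, alpha) {
  arm <- match(data$dose, design$doses)
  narm <- length(design$doses)
  ni <- tabulate(arm, narm)
  ybar <- as.numeric(tapply(data$response, factor(arm, 1:narm), mean))
  N <- sum(ni)
  s2 <- sum((data$response - ybar[arm])^2) / (N - narm)
  df <- N - narm
  k <- narm - 1L

  contrast_for <- function(mu, J) {
    cc <- numeric(narm)
    mbar <- sum(ni[J] * mu[J]) / sum(ni[J])
    cc[J] <- ni[J] * (mu[J] - mbar)
    cc <- cc / sqrt(sum(cc^2))
    if (sum(cc * mu) < 0) cc <- -cc
    cc
  }
  constrained_for <- function(mu, I) {
    best <- NULL
    bobj <- -Inf
    nsub <- length(I)
    for (code in seq_len(2^nsub - 1L)) {
      S <- I[as.logical(bitwAnd(code, 2^(seq_len(nsub) - 1L)))]
      cc <- contrast_for(mu, c(1L, S + 1L))
      if (any(cc[S + 1L] < -1e-12)) next
      obj <- sum(cc * mu) / sqrt(sum(cc^2 / ni))
      if (obj > bobj) { bobj <- obj; best <- cc }
    }
    best
  }

  subsets <- list()
  for (code in seq_len(2^k - 1L))
    subsets[[code]] <- which(as.logical(bitwAnd(code, 2^(0:(k - 1L)))))
  # order: decreasing cardinality then lexicographic
  card <- vapply(subsets, length, integer(1))
  keys <- vapply(subsets, function(s) paste(sprintf("%02d", s), collapse = ""),
                 character(1))
  subsets <- subsets[order(-card, keys)]

  p_I <- numeric(length(subsets))
  for (jj in seq_along(subsets)) {
    I <- subsets[[jj]]
    C <- sapply(models, function(m) {
      mu <- std_response(m, design$doses)
      if (constrained) constrained_for(mu, I)
      else contrast_for(mu, c(1L, I + 1L))
    })
    tt <- as.numeric(crossprod(C, ybar)) / sqrt(s2 * colSums(C^2 / ni))
    V <- crossprod(C, C / ni)
    R <- V / tcrossprod(sqrt(diag(V)))
    # collapse duplicated coordinates (correlation 1)
    keep <- integer(0)
    for (j2 in seq_len(ncol(R))) {
      if (!any(R[keep, j2] >= 1 - 1e-12)) keep <- c(keep, j2)
    }
    qs <- vapply(tt, function(t1) {
      if (length(keep) == 1L) stats::pt(t1, df, lower.tail = FALSE)
      else {
        pr <- withr::with_seed(99L,
          mvtnorm::pmvt(lower = rep(-Inf, length(keep)),
                        upper = rep(t1, length(keep)),
                        df = as.integer(df),
                        corr = R[keep, keep],
                        algorithm = mvtnorm::GenzBretz(maxpts = 50000L,
                                                       abseps = 5e-5)))
        1 - as.numeric(pr)
      }
    }, numeric(1))
    p_I[jj] <- min(qs)
  }
  elem_p <- numeric(k)
  elem_rej <- logical(k)
  for (i in seq_len(k)) {
    has <- vapply(subsets, function(s) i %in% s, logical(1))
    elem_p[i] <- max(p_I[has])
    elem_rej[i] <- all(p_I[has] < alpha)
  }
  list(subsets = subsets, p_I = p_I, elementary_p = elem_p,
       elementary_reject = elem_rej)
}

# Monte-Carlo equicoordinate quantile of max of equicorrelated t variables
# (one-factor representation), for checking critical values.
mc_maxt_quantile <- function(rho, m, df, alpha, nsim = 1e6, seed = 123) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z0 <- stats::rnorm(nsim)
  mx <- rep(-Inf, nsim)
  for (j in seq_len(m))
    mx <- pmax(mx, sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(nsim))
  chi <- sqrt(stats::rchisq(nsim, df) / df)
  as.numeric(stats::quantile(mx / chi, 1 - alpha))
}

# simulate many flat/structured trials and collect summary stats
simulate_summaries <- function(scen, nsim) {
  design <- scen$design
  means <- matrix(NA_real_, nsim, length(design$doses))
  s <- numeric(nsim)
  for (r in seq_len(nsim)) {
    st <- summarize_trial(simulate_trial(scen, r), design)
    means[r, ] <- st$means
    s[r] <- st$s
  }
  list(means = means, s = s)
}

# Independent straight-line removal algebra with an explicit removal order,
# for checking order-invariance of the graph's local levels.
local_levels_ordered <- function(graph, intersection, order) {
  w <- graph$weights
  g <- graph$transitions
  active <- graph$labels
  for (j in order) {
    active <- setdiff(active, j)
    for (l in active) w[l] <- w[l] + w[j] * g[j, l]
    w[j] <- 0
    g2 <- g
    for (l in active) for (m in setdiff(active, l)) {
      den <- 1 - g[l, j] * g[j, l]
      g2[l, m] <- if (den > 1e-12) (g[l, m] + g[l, j] * g[j, m]) / den else 0
    }
    g2[j, ] <- 0; g2[, j] <- 0
    g <- g2
  }
  w[graph$labels[graph$labels %in% intersection]]
}
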