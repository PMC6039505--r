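# Independent oracles used across the suite. These are deliberately naive
# (closed forms, grid searches, numeric integration) and share no code with
# the package internals they check.

# DerSimonian-Laird moment estimator, written out from the closed form:
# Q = sum(w y^2) - (sum(w y))^2 / sum(w) with w = 1/v,
# tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w))).
oracle_dl_tau2 <- function(y, v) {
  w <- 1 / v
  k <- length(y)
  Q <- sum(w * y^2) - sum(w * y)^2 / sum(w)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Restricted log-likelihood of the random-effects model at a given tau2.
oracle_reml_ll <- function(tau2, y, v) {
  wi <- 1 / (v + tau2)
  b <- sum(wi * y) / sum(wi)
  -0.5 * (sum(log(v + tau2)) + log(sum(wi)) + sum(wi * (y - b)^2))
}

# Grid-search maximizer of the restricted likelihood: coarse pass over
# [0, upper], then two refinement passes down to a spacing below 1e-6.
oracle_reml_grid <- function(y, v, upper = NULL) {
  if (is.null(upper)) upper <- max(1, 10 * stats::var(y))
  grid <- seq(0, upper, length.out = 4001)
  for (pass in 1:3) {
    ll <- vapply(grid, oracle_reml_ll, numeric(1), y = y, v = v)
    best <- grid[which.max(ll)]
    step <- grid[2] - grid[1]
    if (step < 1e-6) break
    grid <- seq(max(0, best - step), best + step, length.out = 4001)
  }
  best
}

# Inverse-variance fixed-effect pooled estimate.
oracle_fixed_effect <- function(y, v) sum(y / v) / sum(1 / v)

# Exact gamma/Poisson interval for a single-stratum standardized rate:
# with one stratum the gamma construction must reduce to the classical
# exact Poisson interval for x scaled by 1e5/n.
oracle_single_stratum_ci <- function(x, n, level = 0.95) {
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qgamma(a / 2, shape = x, rate = n)
  hi <- stats::qgamma(1 - a / 2, shape = x + 1, rate = n)
  1e5 * c(lo, hi)
}

# Delta-method interval for r = 1e5 * sum(w exp(beta)) with independent
# normal errors on beta.
oracle_delta_ci <- function(w, beta, sigma, level = 0.95) {
  r <- sum(w * exp(beta))
  se <- sqrt(sum((w * exp(beta) * sigma)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  1e5 * c(r - z * se, r + z * se)
}

# True person-time prevalence (per 100,000) for a cohort entering a stratum
# of width L at its lower bound, with constant onset hazard lam_on and
# mortality hazard lam_dth, censored at L: ratio of expected case-years to
# expected person-years, both by numeric integration.
oracle_persontime_rate <- function(lam_on, lam_dth, L) {
  e_py <- stats::integrate(function(t) exp(-lam_dth * t), 0, L)$value
  e_cy <- stats::integrate(function(t) (1 - exp(-lam_on * t)) * exp(-lam_dth * t),
                           0, L)$value
  1e5 * e_cy / e_py
}

copiah_path <- function() {
  system.file("extdata", "copiah_1978.csv", package = "metaprev")
}
us2010_path <- function() {
  system.file("extdata", "us2010_standard.csv", package = "metaprev")
}
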