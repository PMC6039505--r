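# The composite age-standardized meta-estimate: per-stratum pooled log
# prevalences beta_i from the meta-engine are combined with
# standard-population weights w_i as r = 100,000 * sum_i w_i exp(beta_i).
# Its confidence interval is Monte-Carlo: each stratum's coefficient is
# redrawn as beta_i ~ N(beta_i, se_i^2) independently across strata, r is
# recomputed per draw, and the empirical percentiles are reported.

#' Age-standardized meta-estimate with Monte-Carlo confidence interval
#'
#' Combines per-stratum pooled log prevalences (e.g. one row per sex x
#' 10-year age group from [meta_by_stratum()]) into a single standardized
#' rate using standard-population weights, r = 100,000 * sum(w * exp(beta)).
#' Weights are recomputed from the aligned standard counts, so subsetting to
#' one sex renormalizes automatically; with both sexes present the result is
#' the combined-sexes rate, weighting sex-specific stratum prevalences by
#' sex-specific population counts.
#'
#' @param meta A data frame with columns `age_lo`, `age_hi`, `beta`, `se`
#'   and optionally `sex` (a `re_meta_table` works as is). `se` is the
#'   standard error of the pooled random-effects coefficient, which carries
#'   the between-study variance through the pooling weights.
#' @param std_pop A [standard_population()] whose strata (and sexes, if any)
#'   all match `meta` one-to-one.
#' @param n_draws Monte-Carlo draws per stratum for the interval
#'   (default 1e6, as many as practical; `0` skips the interval).
#' @param seed Integer seed making the interval reproducible.
#' @param level Confidence level.
#' @return An object of class `"meta_std_rate"`: `rate` per 100,000, `ci`,
#'   `level`, `n_draws`, `seed` and the per-stratum `components`
#'   (`sex`, `age_lo`, `age_hi`, `weight`, `beta`, `se`).
#' @examples
#' comp <- data.frame(age_lo = c(45, 55), age_hi = c(55, Inf),
#'                    beta = log(c(0.004, 0.006)), se = c(0.02, 0.02))
#' std <- standard_population(c(45, 55), c(55, Inf), count = c(1e6, 1e6))
#' meta_std_rate(comp, std, n_draws = 1e4, seed = 1)
#' @export
meta_std_rate <- function(meta, std_pop, n_draws = 1e6, seed = NULL,
                          level = 0.95) {
  stopifnot(inherits(std_pop, "std_pop"), level > 0, level < 1, n_draws >= 0)
  meta <- as.data.frame(meta)
  req <- c("age_lo", "age_hi", "beta", "se")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("meta results are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(meta$se < 0)) stop("standard errors must be nonnegative",
                             call. = FALSE)
  idx <- align_strata(std_pop, meta, "standard population", "meta results")
  m <- meta[idx, , drop = FALSE]      # one meta row per standard stratum
  w <- std_pop$count / sum(std_pop$count)
  rate <- 1e5 * sum(w * exp(m$beta))
  ci <- if (n_draws > 0) {
    mc_rate_ci(w, m$beta, m$se, n_draws = n_draws, seed = seed, level = level)
  } else {
    c(NA_real_, NA_real_)
  }
  comp <- data.frame(
    sex = if ("sex" %in% names(std_pop)) std_pop$sex else "combined",
    age_lo = std_pop$age_lo, age_hi = std_pop$age_hi,
    weight = w, beta = m$beta, se = m$se)
  structure(list(rate = rate, ci = ci, level = level,
                 n_draws = as.integer(n_draws), seed = seed,
                 components = comp),
            class = "meta_std_rate")
}

#' Monte-Carlo percentile interval for a weighted exp-combination
#'
#' Draws `beta_i ~ N(beta_i, sigma_i^2)` independently per stratum,
#' recomputes `r = 100000 * sum(w * exp(beta))` for each draw and returns
#' the empirical `(1-level)/2` and `1-(1-level)/2` percentiles
#' (order-statistic percentiles with linear interpolation, R quantile
#' type 7). Deterministic for a fixed `seed`; with all `sigma = 0` the
#' degenerate interval `(r, r)` is returned without drawing.
#'
#' @param w Stratum weights (need not sum to 1; used as given).
#' @param beta Stratum log prevalences.
#' @param sigma Nonnegative standard errors of `beta`.
#' @param n_draws Number of Monte-Carlo draws, at least 1000.
#' @param seed Optional integer seed.
#' @param level Confidence level.
#' @return `c(low, high)` per 100,000.
#' @export
mc_rate_ci <- function(w, beta, sigma, n_draws = 1e6, seed = NULL,
                       level = 0.95) {
  k <- length(w)
  stopifnot(length(beta) == k, length(sigma) == k, level > 0, level < 1)
  if (any(sigma < 0)) stop("sigma must be nonnegative", call. = FALSE)
  if (all(sigma == 0)) {
    r <- 1e5 * sum(w * exp(beta))
    return(c(r, r))
  }
  if (n_draws < 1000) stop("n_draws must be at least 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_draws <- as.integer(n_draws)
  r <- numeric(n_draws)
  for (i in seq_len(k)) {            # stratum-wise to keep memory flat
    r <- r + w[i] * exp(stats::rnorm(n_draws, beta[i], sigma[i]))
  }
  alpha <- 1 - level
  1e5 * stats::quantile(r, probs = c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
}

#' Project case burden onto a population table
#'
#' Applies stratum-specific prevalence rates to a (current or forecast)
#' population structure: expected cases = sum over strata of
#' `(rate_i / 100000) * population_i`, summed over sexes when present.
#' Summaries round to the nearest 1,000; the returned totals are exact.
#'
#' @param rates A data frame with `age_lo`, `age_hi`, `rate` (per 100,000)
#'   and optionally `sex`. A `re_meta_table` works as is.
#' @param projection A [standard_population()]-style table whose `count`
#'   column holds the target-year population.
#' @return A list with `total` (expected cases, full precision),
#'   `total_rounded` (sum of per-stratum rounded expectations, matching
#'   presentation tables) and the per-stratum `table`.
#' @examples
#' rates <- data.frame(age_lo = 45, age_hi = Inf, rate = 572)
#' pop <- standard_population(45, Inf, count = 119e6)
#' project_counts(rates, pop)$total
#' @export
project_counts <- function(rates, projection) {
  stopifnot(inherits(projection, "std_pop"))
  rates <- as.data.frame(rates)
  req <- c("age_lo", "age_hi", "rate")
  miss <- setdiff(req, names(rates))
  if (length(miss)) {
    stop("rates table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(rates$rate < 0)) stop("rates must be nonnegative", call. = FALSE)
  idx <- align_strata(projection, rates, "projection", "rates")
  r <- rates[idx, , drop = FALSE]
  expected <- (r$rate / 1e5) * projection$count
  tab <- data.frame(
    sex = if ("sex" %in% names(projection)) projection$sex else "combined",
    age_lo = projection$age_lo, age_hi = projection$age_hi,
    rate = r$rate, population = projection$count,
    expected = expected, expected_rounded = round(expected))
  list(total = sum(expected), total_rounded = sum(round(expected)),
       table = tab)
}

#' @export
print.meta_std_rate <- function(x, ...) {
  cat("Age-standardized meta-estimate\n")
  cat(sprintf("  rate: %.0f per 100,000", x$rate))
  if (!is.na(x$ci[1])) {
    cat(sprintf(" (%d%% MC CI %.0f-%.0f; %s draws%s)",
                round(100 * x$level), x$ci[1], x$ci[2],
                format(x$n_draws, big.mark = ","),
                if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  }
  cat("\n  strata:\n")
  comp <- x$components
  comp$rate <- 1e5 * exp(comp$beta)
  print(data.frame(sex = comp$sex,
                   stratum = stratum_label(comp$age_lo, comp$age_hi),
                   weight = round(comp$weight, 4),
                   rate = round(comp$rate, 1),
                   se_log = round(comp$se, 4)), row.names = FALSE)
  invisible(x)
}
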