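# Direct standardization of stratified prevalence counts to a standard
# population. The point estimate is the weighted average of stratum rates,
# rate = 100,000 * sum_i E_i / sum_i P_i with expected cases
# E_i = (x_i/n_i) * P_i. Confidence intervals use the gamma method for
# directly standardized rates: the Fay-Feuer construction with the
# Tiwari et al. modification, in which the upper bound's shape adjustment
# uses the mean stratum weight and the mean squared weight rather than the
# maximum weight.

#' Crude prevalence per 100,000
#'
#' @param x Nonnegative integer case count(s).
#' @param n Positive integer denominator(s).
#' @return `100000 * x / n`.
#' @examples
#' crude_rate(4, 2473)
#' @export
crude_rate <- function(x, n) {
  if (any(n <= 0)) stop("undefined rate: denominator must be positive",
                        call. = FALSE)
  if (any(x < 0)) stop("case count must be nonnegative", call. = FALSE)
  1e5 * x / n
}

#' Expected cases in a standard-population stratum
#'
#' The number of cases the study's stratum rate implies in the standard
#' population: `(x/n) * std_count`. Output tables round this to the nearest
#' integer for presentation; all downstream computation keeps full
#' precision.
#'
#' @param x,n Stratum cases and denominator.
#' @param std_count Standard-population count for the stratum.
#' @return Expected case count (full precision).
#' @examples
#' expected_cases(4, 2473, 50137484)  # ~81,096
#' @export
expected_cases <- function(x, n, std_count) {
  if (any(n <= 0)) stop("denominator must be positive", call. = FALSE)
  (x / n) * std_count
}

#' Directly standardized prevalence with gamma confidence interval
#'
#' Standardizes a set of study strata (one study, or one study x sex) to a
#' standard population and attaches a gamma-method confidence interval.
#' Study strata and standard-population strata must align exactly on
#' (sex when present in both, age_lo, age_hi); weights are recomputed from
#' the aligned standard counts, so passing one sex of a two-sex standard
#' population renormalizes automatically.
#'
#' @param study A study table (all rows are used; subset beforehand to
#'   standardize a single study or sex).
#' @param std_pop A [standard_population()].
#' @param level Confidence level, default 0.95.
#' @return An object of class `"std_rate"` with elements `rate`, `ci`,
#'   `level`, `total_expected` (full precision),
#'   `total_expected_rounded` (sum of per-stratum rounded expected cases,
#'   as presented in output tables), `std_total` and a per-stratum `table`.
#' @examples
#' study <- read_study_table(system.file("extdata", "copiah_1978.csv",
#'                                       package = "metaprev"))
#' std <- read_standard_population(system.file("extdata", "us2010_standard.csv",
#'                                             package = "metaprev"))
#' std_rate(study, std)
#' @export
std_rate <- function(study, std_pop, level = 0.95) {
  stopifnot(inherits(std_pop, "std_pop"), level > 0, level < 1)
  study <- as_study_table(study)
  if (!nrow(study)) stop("no study strata supplied", call. = FALSE)
  key <- study
  # a sex-agnostic (all-"combined") standard population may standardize a
  # single-sex study table on age alone
  if (all(std_pop$sex == "combined") && length(unique(study$sex)) == 1) {
    key$sex <- "combined"
  }
  idx <- align_strata(key, std_pop, "study table", "standard population")
  P <- std_pop$count[idx]
  x <- study$cases
  n <- study$population
  E <- expected_cases(x, n, P)
  std_total <- sum(P)
  rate <- 1e5 * sum(E) / std_total
  ci <- gamma_rate_ci(x, n, P, level = level)
  tab <- data.frame(
    sex = study$sex,
    stratum = stratum_label(study$age_lo, study$age_hi),
    age_lo = study$age_lo, age_hi = study$age_hi,
    cases = x, population = n,
    crude_rate = crude_rate(x, n),
    std_count = P,
    expected = E,
    expected_rounded = round(E)
  )
  structure(list(rate = rate, ci = ci, level = level,
                 total_expected = sum(E),
                 total_expected_rounded = sum(round(E)),
                 std_total = std_total, table = tab,
                 ci_method = "gamma (Fay-Feuer, Tiwari modification)"),
            class = "std_rate")
}

#' Gamma confidence interval for a directly standardized rate
#'
#' Implements the gamma interval of Fay and Feuer with the Tiwari et al.
#' modification. With per-stratum weights
#' \eqn{w_i = (P_i / \sum_j P_j) / n_i}, the standardized rate (per person)
#' is \eqn{R = \sum_i w_i x_i} with Poisson variance estimate
#' \eqn{v = \sum_i w_i^2 x_i}. The lower bound is the \eqn{\alpha/2} quantile
#' of a gamma distribution with mean R and variance v (0 when no cases); the
#' upper bound is the \eqn{1-\alpha/2} quantile of a gamma with mean
#' \eqn{R + \bar w} and variance \eqn{v + \overline{w^2}}, where \eqn{\bar w}
#' and \eqn{\overline{w^2}} are the mean weight and mean squared weight
#' (Fay-Feuer use the maximum weight; the Tiwari modification replaces it
#' with these means, giving shorter but still conservative intervals). For a
#' single stratum the construction reduces to the exact Poisson gamma
#' interval.
#'
#' @param x,n Per-stratum cases and denominators.
#' @param std_count Per-stratum standard-population counts.
#' @param level Confidence level.
#' @return `c(low, high)` per 100,000.
#' @export
gamma_rate_ci <- function(x, n, std_count, level = 0.95) {
  stopifnot(length(x) >= 1, level > 0, level < 1)
  if (any(n <= 0)) stop("denominator must be positive", call. = FALSE)
  alpha <- 1 - level
  w <- (std_count / sum(std_count)) / n
  R <- sum(w * x)
  v <- sum(w^2 * x)
  lo <- if (R <= 0) 0 else stats::qgamma(alpha / 2, shape = R^2 / v, rate = R / v)
  wm <- mean(w)
  wm2 <- mean(w^2)
  Ru <- R + wm
  vu <- v + wm2
  hi <- stats::qgamma(1 - alpha / 2, shape = Ru^2 / vu, rate = Ru / vu)
  c(1e5 * lo, 1e5 * hi)
}

#' @export
print.std_rate <- function(x, ...) {
  cat("Directly standardized prevalence\n")
  cat(sprintf("  rate: %.0f per 100,000 (%d%% CI %.0f-%.0f, %s)\n",
              x$rate, round(100 * x$level), x$ci[1], x$ci[2], x$ci_method))
  cat(sprintf("  expected cases: %.0f (sum of rounded: %d) in standard population %.0f\n",
              x$total_expected, x$total_expected_rounded, x$std_total))
  invisible(x)
}

#' @export
summary.std_rate <- function(object, ...) {
  print(object)
  cat("\nPer-stratum detail:\n")
  tab <- object$table
  tab$crude_rate <- round(tab$crude_rate, 1)
  tab$expected <- round(tab$expected, 1)
  print(tab[, c("sex", "stratum", "cases", "population", "crude_rate",
                "std_count", "expected_rounded")], row.names = FALSE)
  invisible(object)
}
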