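# Random-effects meta-analysis of log prevalence across studies, fit
# separately within each sex x age stratum. Each study contributes an
# effect y = ln(x/n) with within-study variance v = 1/x (the large-sample
# Poisson variance of a log rate; a binomial variant (1-p)/x is available).
# Pooling uses inverse-variance weights 1/(v + tau^2), with the
# between-study variance tau^2 estimated by REML (default) or
# DerSimonian-Laird; the fit itself is delegated to metafor::rma.uni.
# Heterogeneity is summarized by Cochran's Q (fixed-effect weights) and
# I^2 = max(0, (Q - (k-1))/Q) * 100, with a Higgins-Thompson test-based
# confidence interval on ln H back-transformed to the I^2 scale.

#' Log-prevalence effect for meta-analysis
#'
#' Converts stratum counts to the per-study effect entering the
#' random-effects model: `y = log(x/n)` with variance `v = 1/x`
#' (Poisson approximation for a rare outcome) or `v = (1-p)/x`
#' (binomial). Zero-case strata carry no information about log prevalence
#' and raise an error of class `"metaprev_zero_cases"`; callers decide
#' whether to exclude the study (see [meta_by_stratum()]).
#'
#' @param x Case count(s), `x >= 1`.
#' @param n Denominator(s).
#' @param variance `"poisson"` (default) or `"binomial"`.
#' @return A data frame with columns `y` and `v`.
#' @examples
#' log_effect(100, 10000)  # y = log(0.01), v = 0.01
#' @export
log_effect <- function(x, n, variance = c("poisson", "binomial")) {
  variance <- match.arg(variance)
  if (any(n <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(x < 0)) stop("case count must be nonnegative", call. = FALSE)
  if (any(x == 0)) {
    cond <- structure(
      class = c("metaprev_zero_cases", "error", "condition"),
      list(message = "zero-case stratum: log prevalence undefined; exclude the study or supply a positive count",
           call = sys.call(-1)))
    stop(cond)
  }
  p <- x / n
  data.frame(y = log(p),
             v = if (variance == "poisson") 1 / x else (1 - p) / x)
}

#' Random-effects meta-analysis of study effects
#'
#' Pools per-study effects (typically log prevalences from [log_effect()])
#' under the additive random-effects model y_j = mu + u_j + e_j,
#' u_j ~ N(0, tau^2), e_j ~ N(0, v_j). The pooled estimate is
#' beta = sum(w* y) / sum(w*) with w*_j = 1/(v_j + tau^2) and
#' SE = sqrt(1/sum(w*)). tau^2 is estimated by restricted maximum
#' likelihood (default) or the DerSimonian-Laird moment estimator; the fit
#' is performed by \pkg{metafor}. A single study returns its own effect
#' with tau^2 = 0 and heterogeneity marked not computable.
#'
#' @param y Numeric effect estimates (one per study).
#' @param v Positive within-study variances.
#' @param method `"REML"` (default) or `"DL"`.
#' @param study_id Optional study labels.
#' @param level Confidence level for the I^2 interval.
#' @return An object of class `"re_meta"` with elements `beta`, `se`,
#'   `tau2`, `Q`, `k`, `I2`, `I2_ci`, `method`, `level` and the input
#'   `data`. `I2` and `I2_ci` are `NA` when `k < 2`.
#' @examples
#' eff <- log_effect(c(120, 95, 150), c(20000, 21000, 19000))
#' fit_random_effects(eff$y, eff$v, method = "DL")
#' @export
fit_random_effects <- function(y, v, method = c("REML", "DL"),
                               study_id = NULL, level = 0.95) {
  method <- match.arg(method)
  k <- length(y)
  if (k == 0) stop("no studies to pool", call. = FALSE)
  if (length(v) != k) stop("y and v differ in length", call. = FALSE)
  if (any(v <= 0)) stop("within-study variances must be positive", call. = FALSE)
  if (is.null(study_id)) study_id <- paste0("study", seq_len(k))

  if (k == 1) {
    beta <- y[1]; se <- sqrt(v[1]); tau2 <- 0; Q <- 0
    I2 <- NA_real_; I2_ci <- c(NA_real_, NA_real_)
  } else {
    fit <- metafor::rma.uni(yi = y, vi = v, method = method)
    beta <- as.numeric(fit$beta)
    se <- fit$se
    tau2 <- fit$tau2
    Q <- fit$QE                      # Cochran's Q with fixed-effect weights
    I2 <- i_squared(Q, k)
    I2_ci <- i_squared_ci(Q, k, level = level)
  }
  structure(list(beta = beta, se = se, tau2 = tau2, Q = Q, k = k,
                 I2 = I2, I2_ci = I2_ci, method = method, level = level,
                 data = data.frame(study_id = study_id, y = y, v = v)),
            class = "re_meta")
}

#' I-squared heterogeneity statistic
#'
#' The percentage of variation across studies attributable to between-study
#' heterogeneity rather than chance: `I2 = max(0, (Q - (k-1))/Q) * 100`,
#' and 0 when Q = 0.
#'
#' @param Q Cochran's Q statistic (nonnegative).
#' @param k Number of studies, `k >= 2`.
#' @return A percentage in \[0, 100\].
#' @examples
#' i_squared(10, 6)  # 50
#' @export
i_squared <- function(Q, k) {
  if (k < 2) stop("I^2 requires at least two studies", call. = FALSE)
  if (Q < 0) stop("Q must be nonnegative", call. = FALSE)
  if (Q == 0) return(0)
  max(0, (Q - (k - 1)) / Q) * 100
}

#' Test-based confidence interval for I-squared
#'
#' Higgins-Thompson interval built on H = sqrt(Q/(k-1)): a normal interval
#' for ln H with standard error
#' \deqn{SE(\ln H) = \frac{1}{2}\,\frac{\ln Q - \ln(k-1)}{\sqrt{2Q} - \sqrt{2k-3}}  \quad (Q > k)}
#' \deqn{SE(\ln H) = \sqrt{\frac{1}{2(k-2)}\Big(1 - \frac{1}{3(k-2)^2}\Big)}  \quad (Q \le k),}
#' back-transformed through `I2 = 100 (H^2 - 1)/H^2` and truncated to
#' \[0, 100\]. For `k = 2` with `Q <= k` the second formula is undefined and
#' the non-informative interval (0, 100) is returned.
#'
#' @param Q Cochran's Q.
#' @param k Number of studies, `k >= 2`.
#' @param level Confidence level.
#' @return `c(low, high)` in percent.
#' @export
i_squared_ci <- function(Q, k, level = 0.95) {
  if (k < 2) stop("I^2 interval requires at least two studies", call. = FALSE)
  if (Q < 0) stop("Q must be nonnegative", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (Q > k) {
    se_lnH <- 0.5 * (log(Q) - log(k - 1)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    se_lnH <- sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    return(c(0, 100))
  }
  lnH <- 0.5 * log(max(Q, .Machine$double.xmin) / (k - 1))
  H_lo <- max(1, exp(lnH - z * se_lnH))
  H_hi <- max(1, exp(lnH + z * se_lnH))
  to_i2 <- function(H) 100 * (H^2 - 1) / H^2
  pmin(pmax(c(to_i2(H_lo), to_i2(H_hi)), 0), 100)
}

#' Per-stratum random-effects meta-analysis of a multi-study table
#'
#' Splits a study table by sex and age stratum and fits [fit_random_effects()]
#' within each cell, pooling log prevalence across studies. Zero-case rows
#' are excluded from their cell with a warning (no continuity correction).
#' Rows whose `study_type` column equals `"cohort"` (longitudinal
#' person-time studies, analysed by [person_time_prevalence()] instead) are
#' never entered into the meta-fit.
#'
#' @param study A study table covering several studies on a common stratum
#'   partition (use [rebin_counts()] first if needed).
#' @param method tau^2 estimator, `"REML"` or `"DL"`.
#' @param variance Within-study variance model, see [log_effect()].
#' @param level Confidence level for I^2 intervals.
#' @return A data frame of class `c("re_meta_table", "data.frame")` with one
#'   row per sex x stratum: `sex`, `age_lo`, `age_hi`, `k`, `beta`, `se`,
#'   `tau2`, `Q`, `I2`, `I2_lo`, `I2_hi`, `prevalence = exp(beta)` and
#'   `rate` per 100,000.
#' @export
meta_by_stratum <- function(study, method = c("REML", "DL"),
                            variance = c("poisson", "binomial"),
                            level = 0.95) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  study <- as_study_table(study)
  if ("study_type" %in% names(study)) {
    drop <- study$study_type %in% "cohort"
    if (any(drop)) {
      message("excluding cohort-type study rows from meta-analysis: ",
              paste(unique(study$study_id[drop]), collapse = ", "))
      study <- study[!drop, , drop = FALSE]
    }
  }
  zero <- study$cases == 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " zero-case stratum row(s) from the meta-analysis (studies: ",
            paste(unique(study$study_id[zero]), collapse = ", "), ")",
            call. = FALSE)
    study <- study[!zero, , drop = FALSE]
  }
  if (!nrow(study)) stop("no usable rows for meta-analysis", call. = FALSE)
  cells <- split(study, list(study$sex, study$age_lo, study$age_hi),
                 drop = TRUE)
  rows <- lapply(cells, function(g) {
    eff <- log_effect(g$cases, g$population, variance = variance)
    fit <- fit_random_effects(eff$y, eff$v, method = method,
                              study_id = g$study_id, level = level)
    data.frame(sex = g$sex[1], age_lo = g$age_lo[1], age_hi = g$age_hi[1],
               k = fit$k, beta = fit$beta, se = fit$se, tau2 = fit$tau2,
               Q = fit$Q, I2 = fit$I2, I2_lo = fit$I2_ci[1],
               I2_hi = fit$I2_ci[2])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sex, out$age_lo), , drop = FALSE]
  out$prevalence <- exp(out$beta)
  out$rate <- 1e5 * out$prevalence
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "variance") <- variance
  class(out) <- c("re_meta_table", "data.frame")
  out
}

#' @export
print.re_meta <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  pooled effect: %.4f (SE %.4f)  exp(beta) = %.6g\n",
              x$beta, x$se, exp(x$beta)))
  cat(sprintf("  tau^2 = %.6g, Q = %.4g\n", x$tau2, x$Q))
  if (x$k >= 2) {
    cat(sprintf("  I^2 = %.1f%% (%d%% CI %.1f-%.1f)\n", x$I2,
                round(100 * x$level), x$I2_ci[1], x$I2_ci[2]))
  } else {
    cat("  heterogeneity not computable (single study)\n")
  }
  invisible(x)
}

#' @export
coef.re_meta <- function(object, ...) c(beta = object$beta)

#' @export
vcov.re_meta <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("beta", "beta"))
}
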