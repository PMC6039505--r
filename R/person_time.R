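# Person-time prevalence for a longitudinal cohort followed over decades
# (one fixed cohort of subjects, diagnoses accumulating as it ages). Within
# an age stratum, every year a subject is alive contributes to the
# person-years at risk (denominator) and every year lived with a diagnosis
# contributes to the case-years (numerator); the prevalence is their ratio.
# Because years contributed by the same subject are dependent, the
# confidence interval resamples subjects (with all their person-time) with
# replacement and takes empirical percentiles.

# Per-subject overlap of follow-up with [lo, hi), and of the diagnosed
# portion of follow-up with the same window. Diagnosis is absorbing: case
# time runs from diagnosis (or entry, if diagnosed before entry) to exit.
subject_time <- function(cohort, age_lo, age_hi) {
  py <- pmax(0, pmin(cohort$exit_age, age_hi) - pmax(cohort$entry_age, age_lo))
  dx <- cohort$diagnosis_age
  cy <- ifelse(is.na(dx), 0,
               pmax(0, pmin(cohort$exit_age, age_hi) -
                      pmax(dx, cohort$entry_age, age_lo)))
  list(py = py, cy = cy)
}

#' Person-time prevalence within an age stratum
#'
#' For each subject, person-years are the overlap of the follow-up interval
#' \[entry_age, exit_age\] with the stratum \[age_lo, age_hi); case-years are
#' the diagnosed part of that overlap (diagnosis is treated as absorbing, so
#' case time runs from the diagnosis age — or entry, for subjects prevalent
#' at entry — to exit). The prevalence is
#' `100000 * sum(case_years) / sum(person_years)`. Ages may be fractional.
#'
#' @param cohort A cohort table (see [read_cohort_table()]).
#' @param age_lo,age_hi Stratum bounds, exclusive upper (`Inf` allowed), so
#'   the 65-74 stratum is `age_lo = 65, age_hi = 75`.
#' @param n_boot Number of bootstrap replicates for the confidence interval;
#'   `0` (default) skips it. At least 200 otherwise.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return An object of class `"pt_prev"`: `person_years`, `case_years`,
#'   `rate` per 100,000, `ci`, `n_boot`, `seed`, `level`, `n_subjects` and
#'   the stratum bounds.
#' @examples
#' cohort <- as_cohort_table(data.frame(subject_id = "a", entry_age = 60,
#'                                      exit_age = 70, diagnosis_age = 68))
#' person_time_prevalence(cohort, 65, 75)  # 5 person-years, 2 case-years
#' @export
person_time_prevalence <- function(cohort, age_lo, age_hi, n_boot = 0,
                                   seed = NULL, level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"), age_lo < age_hi)
  st <- subject_time(cohort, age_lo, age_hi)
  total_py <- sum(st$py)
  if (total_py <= 0) {
    stop("undefined rate: no person-time falls in stratum ",
         stratum_label(age_lo, age_hi), call. = FALSE)
  }
  rate <- 1e5 * sum(st$cy) / total_py
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- boot_percentile_ci(st$py, st$cy, n_boot = n_boot, seed = seed,
                             level = level)
  }
  structure(list(age_lo = age_lo, age_hi = age_hi,
                 person_years = total_py, case_years = sum(st$cy),
                 rate = rate, ci = ci, n_boot = as.integer(n_boot),
                 seed = seed, level = level, n_subjects = nrow(cohort)),
            class = "pt_prev")
}

#' Bootstrap percentile interval for a person-time prevalence
#'
#' Resamples subjects (not person-years) with replacement, recomputes the
#' person-time rate for each replicate and returns the empirical percentile
#' interval. A replicate whose resampled subjects contribute no person-time
#' to the stratum is redrawn, up to 100 attempts per replicate, after which
#' an error is raised.
#'
#' @inheritParams person_time_prevalence
#' @param n_boot Number of bootstrap replicates, at least 200
#'   (default 10000).
#' @return `c(low, high)` per 100,000.
#' @export
pt_bootstrap_ci <- function(cohort, age_lo, age_hi, n_boot = 10000,
                            seed = NULL, level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  st <- subject_time(cohort, age_lo, age_hi)
  boot_percentile_ci(st$py, st$cy, n_boot = n_boot, seed = seed,
                     level = level)
}

boot_percentile_ci <- function(py, cy, n_boot, seed = NULL, level = 0.95) {
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  if (sum(py) <= 0) stop("no person-time to resample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(py)
  n_boot <- as.integer(n_boot)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  pys <- colSums(matrix(py[idx], nrow = n))
  cys <- colSums(matrix(cy[idx], nrow = n))
  tries <- 0
  while (any(pys <= 0)) {
    tries <- tries + 1
    if (tries > 100) {
      stop("bootstrap failed: replicates with zero person-time persist",
           call. = FALSE)
    }
    bad <- which(pys <= 0)
    re <- matrix(sample.int(n, n * length(bad), replace = TRUE), nrow = n)
    pys[bad] <- colSums(matrix(py[re], nrow = n))
    cys[bad] <- colSums(matrix(cy[re], nrow = n))
  }
  alpha <- 1 - level
  1e5 * stats::quantile(cys / pys, probs = c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
}

#' @export
print.pt_prev <- function(x, ...) {
  cat(sprintf("Person-time prevalence, stratum %s\n",
              stratum_label(x$age_lo, x$age_hi)))
  cat(sprintf("  %.1f case-years / %.1f person-years (%d subjects)\n",
              x$case_years, x$person_years, x$n_subjects))
  cat(sprintf("  rate: %.0f per 100,000", x$rate))
  if (!is.na(x$ci[1])) {
    cat(sprintf(" (%d%% bootstrap CI %.0f-%.0f, %d replicates%s)",
                round(100 * x$level), x$ci[1], x$ci[2], x$n_boot,
                if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  }
  cat("\n")
  invisible(x)
}
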