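# Simulators generating data with the statistical structure the estimators
# assume: (i) multi-study stratified count tables with lognormal
# between-study heterogeneity on the log-prevalence scale and Poisson
# sampling of cases around each study's stratum-specific expectation, and
# (ii) an aging closed cohort with exponential disease onset and mortality.
# Both are deterministic under a fixed seed; per-study streams are derived
# by sequential draws under the single scenario seed.

#' Define a multi-study simulation scenario
#'
#' @param age_lo,age_hi Stratum bounds of the common partition.
#' @param log_prev True log prevalence per stratum (one value per stratum);
#'   `exp(log_prev)` must lie in (0, 1).
#' @param tau Between-study standard deviation on the log-prevalence scale
#'   (`tau >= 0`).
#' @param n_studies Number of studies.
#' @param size Stratum denominators: a scalar, a vector of length
#'   `n_strata`, or an `n_studies x n_strata` matrix.
#' @param sex Sex label for the generated rows (default `"combined"`).
#' @param seed Integer seed (mandatory: scenarios are reproducible objects).
#' @param model Count model: `"poisson"` (default, matching the `v = 1/x`
#'   meta-variance) or `"binomial"` for sensitivity checks.
#' @return An object of class `"sim_scenario"`.
#' @examples
#' sim_scenario(c(45, 55), c(55, Inf), log_prev = log(c(0.002, 0.01)),
#'              tau = 0.1, n_studies = 4, size = 50000, seed = 7)
#' @export
sim_scenario <- function(age_lo, age_hi, log_prev, tau = 0, n_studies,
                         size, sex = "combined", seed,
                         model = c("poisson", "binomial")) {
  model <- match.arg(model)
  n_strata <- length(age_lo)
  stopifnot(length(age_hi) == n_strata, length(log_prev) == n_strata,
            tau >= 0, n_studies >= 1, !missing(seed))
  validate_strata(age_lo, age_hi, where = "scenario strata")
  if (any(!is.finite(log_prev)) || any(log_prev >= 0)) {
    stop("log_prev must give prevalences strictly inside (0, 1)",
         call. = FALSE)
  }
  size <- if (is.matrix(size)) size else
    matrix(size, nrow = n_studies, ncol = n_strata, byrow = TRUE)
  if (!all(dim(size) == c(n_studies, n_strata))) {
    stop("size must be scalar, length n_strata, or n_studies x n_strata",
         call. = FALSE)
  }
  if (any(size < 1)) stop("denominators must be >= 1", call. = FALSE)
  structure(list(age_lo = age_lo, age_hi = age_hi, log_prev = log_prev,
                 tau = tau, n_studies = as.integer(n_studies),
                 size = size, sex = sex, seed = as.integer(seed),
                 model = model),
            class = "sim_scenario")
}

#' Simulate a multi-study stratified count table
#'
#' For every study j and stratum i an independent study effect
#' `delta_ij ~ N(0, tau^2)` shifts the log prevalence, and the case count is
#' drawn as `Poisson(n_ij * exp(log_prev_i + delta_ij))` truncated at the
#' denominator (or `Binomial(n_ij, exp(...))` under the binomial model). A
#' cell whose expected count exceeds its denominator is redrawn a limited
#' number of times before the scenario is declared infeasible.
#'
#' @param scenario A [sim_scenario()].
#' @return A study table with studies labelled `"study01"`, `"study02"`, ...
#' @export
simulate_multistudy <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n_strata <- length(scenario$age_lo)
  rows <- vector("list", scenario$n_studies)
  for (j in seq_len(scenario$n_studies)) {
    n <- scenario$size[j, ]
    delta <- stats::rnorm(n_strata, 0, scenario$tau)
    p <- exp(scenario$log_prev + delta)
    tries <- 0
    while (any(n * p > n)) {        # prevalence drifted above 1
      tries <- tries + 1
      if (tries > 50) {
        stop("scenario infeasible: expected count exceeds denominator ",
             "persistently (tau too large for log_prev)", call. = FALSE)
      }
      bad <- which(n * p > n)
      delta[bad] <- stats::rnorm(length(bad), 0, scenario$tau)
      p <- exp(scenario$log_prev + delta)
    }
    cases <- if (scenario$model == "poisson") {
      pmin(stats::rpois(n_strata, n * p), n)
    } else {
      stats::rbinom(n_strata, n, p)
    }
    rows[[j]] <- data.frame(
      study_id = sprintf("study%02d", j), sex = scenario$sex,
      age_lo = scenario$age_lo, age_hi = scenario$age_hi,
      cases = cases, population = n)
  }
  as_study_table(do.call(rbind, rows))
}

#' Simulate an aging closed cohort
#'
#' Each subject enters at an age drawn uniformly from `entry_age` (or at a
#' fixed age if a single value is given), faces a constant disease-onset
#' hazard and a constant mortality hazard from entry (independent
#' exponential times), and is followed until death or `max_follow` years,
#' whichever comes first. Onset is recorded only if it occurs during
#' follow-up; disease is absorbing.
#'
#' @param n_subjects Number of subjects.
#' @param entry_age A single entry age or a length-2 range for uniform
#'   entry ages.
#' @param onset_hazard,mortality_hazard Constant per-year hazards
#'   (`>= 0`; 0 disables the event).
#' @param max_follow Administrative censoring time in years.
#' @param seed Integer seed.
#' @return A cohort table (see [read_cohort_table()]).
#' @examples
#' simulate_cohort(5, entry_age = 65, onset_hazard = 0.02,
#'                 mortality_hazard = 0.05, max_follow = 20, seed = 3)
#' @export
simulate_cohort <- function(n_subjects, entry_age, onset_hazard,
                            mortality_hazard, max_follow, seed) {
  stopifnot(n_subjects >= 1, onset_hazard >= 0, mortality_hazard >= 0,
            max_follow > 0, !missing(seed))
  set.seed(as.integer(seed))
  entry <- if (length(entry_age) == 2) {
    stats::runif(n_subjects, entry_age[1], entry_age[2])
  } else {
    rep(entry_age, n_subjects)
  }
  death_t <- if (mortality_hazard > 0) {
    stats::rexp(n_subjects, mortality_hazard)
  } else {
    rep(Inf, n_subjects)
  }
  onset_t <- if (onset_hazard > 0) {
    stats::rexp(n_subjects, onset_hazard)
  } else {
    rep(Inf, n_subjects)
  }
  follow <- pmin(death_t, max_follow)
  diagnosis <- ifelse(onset_t < follow, entry + onset_t, NA_real_)
  as_cohort_table(data.frame(
    subject_id = sprintf("subj%05d", seq_len(n_subjects)),
    entry_age = entry, exit_age = entry + follow,
    diagnosis_age = diagnosis))
}
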