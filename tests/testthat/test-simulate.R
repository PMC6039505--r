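test_that("scenarios validate their inputs", {
  expect_error(sim_scenario(45, 55, log_prev = 0.1, tau = 0, n_studies = 2,
                            size = 100, seed = 1), "inside \\(0, 1\\)")
  expect_error(sim_scenario(45, 55, log_prev = log(0.01), tau = -1,
                            n_studies = 2, size = 100, seed = 1))
  expect_error(sim_scenario(c(45, 50), c(55, 60), log_prev = log(c(0.01, 0.01)),
                            tau = 0, n_studies = 2, size = 100, seed = 1),
               "overlap")
})

test_that("multi-study simulation is deterministic under a fixed seed", {
  sc <- sim_scenario(c(45, 55), c(55, Inf), log_prev = log(c(0.002, 0.01)),
                     tau = 0.2, n_studies = 4, size = 20000, seed = 77)
  expect_identical(as.data.frame(simulate_multistudy(sc)),
                   as.data.frame(simulate_multistudy(sc)))
})

test_that("simulated counts have Poisson moments at tau = 0", {
  # 10,000 study replicates of one stratum with n = 1e6, p = 0.005:
  # mean case count must sit within 3 standard errors of 5,000
  sc <- sim_scenario(45, Inf, log_prev = log(0.005), tau = 0,
                     n_studies = 10000, size = 1e6, seed = 42)
  tab <- simulate_multistudy(sc)
  se <- sqrt(5000 / 10000)
  expect_lt(abs(mean(tab$cases) - 5000), 3 * se)
  # and the variance should be close to the mean (Poisson)
  expect_equal(var(tab$cases) / mean(tab$cases), 1, tolerance = 0.05)
})

test_that("binomial model caps counts at the denominator", {
  sc <- sim_scenario(45, Inf, log_prev = log(0.4), tau = 0,
                     n_studies = 200, size = 50, seed = 9, model = "binomial")
  tab <- simulate_multistudy(sc)
  expect_true(all(tab$cases <= tab$population))
})

test_that("cohort simulation honours degenerate hazards", {
  none <- simulate_cohort(100, entry_age = 65, onset_hazard = 0,
                          mortality_hazard = 0.05, max_follow = 10, seed = 3)
  expect_true(all(is.na(none$diagnosis_age)))
  immortal <- simulate_cohort(100, entry_age = c(50, 60), onset_hazard = 0.02,
                              mortality_hazard = 0, max_follow = 10, seed = 3)
  expect_equal(immortal$exit_age, immortal$entry_age + 10)
  expect_identical(as.data.frame(immortal), as.data.frame(
    simulate_cohort(100, entry_age = c(50, 60), onset_hazard = 0.02,
                    mortality_hazard = 0, max_follow = 10, seed = 3)))
})

test_that("simulated cohorts reproduce the closed-form person-time rate", {
  lam_on <- 0.02; lam_dth <- 0.05; L <- 10
  cohort <- simulate_cohort(5000, entry_age = 65, onset_hazard = lam_on,
                            mortality_hazard = lam_dth, max_follow = L,
                            seed = 12)
  fit <- person_time_prevalence(cohort, 65, 65 + L)
  truth <- oracle_persontime_rate(lam_on, lam_dth, L)
  # Monte-Carlo SE of the ratio estimator from the per-subject influence
  py <- pmin(cohort$exit_age - cohort$entry_age, L)
  cy <- ifelse(is.na(cohort$diagnosis_age), 0,
               cohort$exit_age - cohort$diagnosis_age)
  infl <- cy - (fit$rate / 1e5) * py
  se <- 1e5 * sqrt(length(py) * var(infl)) / sum(py)
  expect_lt(abs(fit$rate - truth), 3 * se)
})
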