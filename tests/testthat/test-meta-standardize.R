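test_that("the composite rate is the weighted sum of exponentiated coefficients", {
  one <- data.frame(age_lo = 45, age_hi = Inf, beta = log(0.00572), se = 0)
  sp1 <- standard_population(45, Inf, 1e6)
  expect_equal(meta_std_rate(one, sp1, n_draws = 0)$rate, 572)

  two <- data.frame(age_lo = c(45, 55), age_hi = c(55, Inf),
                    beta = log(c(0.004, 0.006)), se = c(0, 0))
  sp2 <- standard_population(c(45, 55), c(55, Inf), c(5e6, 5e6))
  expect_equal(meta_std_rate(two, sp2, n_draws = 0)$rate, 500)
})

test_that("zero coefficient uncertainty gives a degenerate interval", {
  expect_equal(mc_rate_ci(c(0.4, 0.6), log(c(0.004, 0.006)), c(0, 0)),
               rep(1e5 * (0.4 * 0.004 + 0.6 * 0.006), 2))
  two <- data.frame(age_lo = c(45, 55), age_hi = c(55, Inf),
                    beta = log(c(0.004, 0.006)), se = c(0, 0))
  sp <- standard_population(c(45, 55), c(55, Inf), c(5e6, 5e6))
  fit <- meta_std_rate(two, sp, n_draws = 1e4, seed = 1)
  expect_equal(fit$ci, c(fit$rate, fit$rate))
})

test_that("increasing any stratum coefficient strictly increases the rate", {
  sp <- standard_population(c(45, 55, 65), c(55, 65, Inf), c(4e6, 3e6, 2e6))
  base <- data.frame(age_lo = c(45, 55, 65), age_hi = c(55, 65, Inf),
                     beta = log(c(0.002, 0.005, 0.012)), se = 0)
  r0 <- meta_std_rate(base, sp, n_draws = 0)$rate
  for (i in 1:3) {
    up <- base
    up$beta[i] <- up$beta[i] + 0.01
    expect_gt(meta_std_rate(up, sp, n_draws = 0)$rate, r0)
  }
})

test_that("the Monte-Carlo interval is reproducible and brackets the estimate", {
  sp <- standard_population(c(45, 55, 65), c(55, 65, Inf), c(4e6, 3e6, 2e6))
  comp <- data.frame(age_lo = c(45, 55, 65), age_hi = c(55, 65, Inf),
                     beta = log(c(0.002, 0.005, 0.012)),
                     se = c(0.03, 0.02, 0.04))
  f1 <- meta_std_rate(comp, sp, n_draws = 2e4, seed = 99)
  f2 <- meta_std_rate(comp, sp, n_draws = 2e4, seed = 99)
  expect_identical(f1$ci, f2$ci)
  expect_lt(f1$ci[1], f1$rate)
  expect_gt(f1$ci[2], f1$rate)
})

test_that("the Monte-Carlo interval agrees with the delta method for small errors", {
  w <- c(0.5, 0.3, 0.2)
  beta <- log(c(0.003, 0.006, 0.015))
  sigma <- c(0.05, 0.04, 0.03)
  mc <- mc_rate_ci(w, beta, sigma, n_draws = 2e5, seed = 4)
  dm <- oracle_delta_ci(w, beta, sigma)
  expect_equal(mc[1], dm[1], tolerance = 0.02)
  expect_equal(mc[2], dm[2], tolerance = 0.02)
})

test_that("missing strata abort the composite with an alignment error", {
  sp <- standard_population(c(45, 55), c(55, Inf), c(5e6, 5e6))
  one <- data.frame(age_lo = 45, age_hi = 55, beta = log(0.004), se = 0.1)
  expect_error(meta_std_rate(one, sp, n_draws = 0), "alignment failed")
})

test_that("projections apply stratum rates to population counts", {
  study <- read_study_table(copiah_path())
  std <- read_standard_population(us2010_path())
  rates <- data.frame(sex = study$sex, age_lo = study$age_lo,
                      age_hi = study$age_hi,
                      rate = crude_rate(study$cases, study$population))
  proj <- project_counts(rates, std)
  expect_equal(proj$total_rounded, 429063)
  expect_equal(proj$total, 429063, tolerance = 1e-5)

  zero <- transform(rates, rate = 0)
  expect_equal(project_counts(zero, std)$total, 0)
  expect_error(project_counts(rates[-1, ], std), "alignment failed")
})
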