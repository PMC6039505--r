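test_that("crude rates follow the definition and reject n = 0", {
  expect_equal(crude_rate(0, 1000), 0)
  expect_equal(crude_rate(1000, 1000), 1e5)
  expect_equal(crude_rate(4, 2473), 1e5 * 4 / 2473)
  expect_error(crude_rate(1, 0), "undefined rate")
})

test_that("expected cases match the published worked example after rounding", {
  expect_equal(round(expected_cases(4, 2473, 50137484)), 81096)
  expect_equal(round(expected_cases(8, 1235, 11616910)), 75251)
  expect_equal(expected_cases(0, 500, 1e6), 0)
})

test_that("the directly standardized rate is the expected-case ratio", {
  # hand arithmetic: 1e5 * (1 + 9) / 400 = 2500
  tab <- as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = c(45, 55), age_hi = c(55, 65),
    cases = c(1, 3), population = c(100, 100)))
  sp <- standard_population(c(45, 55), c(55, 65), c(100, 300))
  fit <- std_rate(tab, sp)
  expect_equal(fit$rate, 2500)
  # conservation: sum(E) = rate * sum(P) / 1e5
  expect_lt(abs(fit$total_expected - fit$rate * fit$std_total / 1e5), 1e-9)
  # convex combination of stratum rates
  cr <- crude_rate(tab$cases, tab$population)
  expect_gte(fit$rate, min(cr))
  expect_lte(fit$rate, max(cr))
})

test_that("identical stratum rates pass through unchanged (convexity identity)", {
  tab <- as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = c(45, 55, 65),
    age_hi = c(55, 65, Inf), cases = c(5, 10, 20),
    population = c(500, 1000, 2000)))   # all rates = 1000 per 1e5
  sp <- standard_population(c(45, 55, 65), c(55, 65, Inf), c(7, 2, 11) * 1e6)
  expect_equal(std_rate(tab, sp)$rate, 1000)
})

test_that("equal weights reduce the standardized rate to the mean stratum rate", {
  tab <- as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = c(45, 55, 65),
    age_hi = c(55, 65, Inf), cases = c(2, 9, 40),
    population = c(1000, 3000, 5000)))
  sp <- standard_population(c(45, 55, 65), c(55, 65, Inf), rep(1e6, 3))
  expect_equal(std_rate(tab, sp)$rate,
               mean(crude_rate(tab$cases, tab$population)))
})

test_that("rate and interval are invariant to rescaling the standard counts", {
  tab <- as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = c(45, 55), age_hi = c(55, Inf),
    cases = c(3, 17), population = c(1200, 900)))
  sp1 <- standard_population(c(45, 55), c(55, Inf), c(2e6, 1e6))
  sp2 <- standard_population(c(45, 55), c(55, Inf), c(2e6, 1e6) * 1000)
  f1 <- std_rate(tab, sp1)
  f2 <- std_rate(tab, sp2)
  expect_equal(f1$rate, f2$rate)
  expect_equal(f1$ci, f2$ci)
})

test_that("the gamma interval reduces to the exact Poisson interval for one stratum", {
  ci <- gamma_rate_ci(10, 1000, 5e6)
  expect_equal(ci, oracle_single_stratum_ci(10, 1000), tolerance = 1e-12)
  # interval brackets the point estimate
  expect_lt(ci[1], crude_rate(10, 1000))
  expect_gt(ci[2], crude_rate(10, 1000))
})

test_that("scaling all counts up shrinks the gamma interval (precision monotonicity)", {
  x <- c(3, 8); n <- c(1000, 2000); P <- c(4e6, 2e6)
  w1 <- diff(gamma_rate_ci(x, n, P))
  w2 <- diff(gamma_rate_ci(x * 100, n * 100, P))
  expect_lt(w2, w1)
})

test_that("zero total cases give a zero lower bound and a finite upper bound", {
  ci <- gamma_rate_ci(c(0, 0), c(1000, 2000), c(1e6, 1e6))
  expect_equal(ci[1], 0)
  expect_gt(ci[2], 0)
  expect_true(is.finite(ci[2]))
  fit <- std_rate(as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = c(45, 55), age_hi = c(55, 65),
    cases = c(0, 0), population = c(1000, 2000))),
    standard_population(c(45, 55), c(55, 65), c(1e6, 1e6)))
  expect_equal(fit$rate, 0)
  expect_equal(fit$ci[1], 0)
})

test_that("stratum misalignment raises an informative error", {
  tab <- as_study_table(data.frame(
    study_id = "s", sex = "combined", age_lo = 45, age_hi = 55,
    cases = 1, population = 100))
  sp <- standard_population(c(45, 60), c(60, Inf), c(1e6, 1e6))
  expect_error(std_rate(tab, sp), "alignment failed")
})
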