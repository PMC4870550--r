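test_that("cumulative hazards match the closed forms", {
  m3 <- hazard_scenario("M3")
  expect_equal(cumulative_hazard(m3, 1, 2), 0.3)
  expect_equal(cumulative_hazard(m3, 0, 2), 0.5)
  for (m in c("M0", "M1", "M2", "M3", "M4")) {
    scn <- hazard_scenario(m)
    expect_equal(cumulative_hazard(scn, 1, 0), 0)
    expect_equal(cumulative_hazard(scn, 0, c(1, 3)),
                 scn$baseline_rate * c(1, 3))
  }
  m2 <- hazard_scenario("M2", baseline_rate = 0.25)
  expect_equal(cumulative_hazard(m2, 1, 0.5), 0.125)
  expect_equal(cumulative_hazard(m2, 1, 2), 0.25 * (0.7 + exp(-1.2) * 1.3))
  expect_error(cumulative_hazard(m3, 1, -1), "negative")

  # custom quadrature agrees with the closed form
  cu <- hazard_scenario("custom", baseline_rate = 0.25,
                        hazard_ratio = function(t) 0.1 + 0.5 * t)
  expect_equal(cumulative_hazard(cu, 1, c(0.5, 2, 5)),
               cumulative_hazard(m3, 1, c(0.5, 2, 5)), tolerance = 1e-9)
})

test_that("failure times are inverse-transform draws from the model", {
  set.seed(41)
  m0 <- hazard_scenario("M0", baseline_rate = 0.25)
  expect_equal(mean(sample_failure_time(m0, 1, 1e5)), 4, tolerance = 0.05)

  m3 <- hazard_scenario("M3")
  tt <- sample_failure_time(m3, 1, 1e5)
  expect_equal(mean(tt > 2), exp(-0.3), tolerance = 0.005)

  # closed-form quadratic inversion vs the bisection path (custom scenario)
  cu <- hazard_scenario("custom", baseline_rate = 0.25,
                        hazard_ratio = function(t) 0.1 + 0.5 * t)
  e <- rexp(1e3)
  expect_equal(bayeshaz:::invert_chaz(m3, 1, e),
               bayeshaz:::invert_chaz(cu, 1, e), tolerance = 1e-8)

  # empirical survival matches exp(-Lambda) on a grid for every model:
  # with 100 comparisons a rare 3-sigma excursion is expected, so allow at
  # most two mild exceedances and none beyond 4 sigma
  n_exceed <- 0
  for (m in c("M0", "M1", "M2", "M3", "M4")) {
    scn <- hazard_scenario(m)
    for (g in 0:1) {
      tt <- sample_failure_time(scn, g, 1e5)
      grid <- seq(0.5, 5, length.out = 10)
      s_true <- exp(-cumulative_hazard(scn, g, grid))
      s_emp <- vapply(grid, function(u) mean(tt > u), numeric(1))
      se <- pmax(sqrt(s_true * (1 - s_true) / 1e5), 1e-3 / 3)
      n_exceed <- n_exceed + sum(abs(s_emp - s_true) >= 3 * se)
      expect_true(all(abs(s_emp - s_true) < 4 * se))
    }
  }
  expect_lte(n_exceed, 2)
})

test_that("censoring calibration hits its target and is monotone", {
  m0 <- hazard_scenario("M0", baseline_rate = 0.25)
  th <- calibrate_censoring(m0, 0.3)
  set.seed(42)
  tt <- sample_failure_time(m0, 0, 1e5)
  cc <- bayeshaz:::sample_censoring(1e5, th, m0$tau)
  expect_equal(mean(tt > cc), 0.3, tolerance = 0.01)

  ths <- vapply(c(0.3, 0.5, 0.7), function(tg) calibrate_censoring(m0, tg),
                numeric(1))
  expect_true(all(diff(ths) > 0))

  expect_identical(calibrate_censoring(m0, 0), -Inf)
  expect_equal(bayeshaz:::sample_censoring(5, -Inf, 6), rep(6, 5))

  # below the administrative-censoring floor: informative error
  m2 <- hazard_scenario("M2", baseline_rate = 0.25)
  expect_error(calibrate_censoring(m2, 0.3), "achievable")
})

test_that("simulated datasets respect balance, the horizon, and the
           censoring target", {
  scn <- hazard_scenario("M0")
  set.seed(43)
  ds <- simulate_survival(scn, 1e4)
  expect_equal(as.integer(table(ds$data$group)), c(5000L, 5000L))
  expect_true(all(ds$data$time <= scn$tau))
  expect_equal(mean(ds$data$event == 0), 0.3, tolerance = 0.012)

  expect_message(ds5 <- simulate_survival(scn, 5, seed = 2), "odd n")
  expect_equal(sum(ds5$data$group == 0), 3)

  # group-0 KM tracks the exponential baseline, group-1 KM tracks the M1
  # proportional-hazards survival curve
  m1 <- hazard_scenario("M1")
  ds1 <- simulate_survival(m1, 1e4, seed = 44)
  grid <- seq(0.2, 4, length.out = 25)
  km0 <- kaplan_meier(ds1, group = 0)
  km1 <- kaplan_meier(ds1, group = 1)
  expect_lt(max(abs(km0$fun(grid) - exp(-m1$baseline_rate * grid))), 0.02)
  expect_lt(max(abs(km1$fun(grid) - exp(-2 * m1$baseline_rate * grid))), 0.02)

  # datasets at moderate censoring virtually always admit a knot interval
  th <- calibrate_censoring(scn, 0.3)
  ok <- vapply(1:50, function(r) {
    d <- simulate_survival(scn, 100, seed = 600 + r, theta = th)
    !inherits(try(knot_interval(d), silent = TRUE), "try-error")
  }, logical(1))
  expect_true(all(ok))
})

test_that("event indicator follows delta = I(T <= C)", {
  # deterministic check through the sampler with censoring at tau only
  scn <- hazard_scenario("M0", censor_rate = 0)
  set.seed(45)
  ds <- simulate_survival(scn, 200, theta = -Inf)
  expect_true(all(ds$data$event[ds$data$time < scn$tau] == 1))
  expect_true(all(ds$data$event[ds$data$time == scn$tau] == 0))
})
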