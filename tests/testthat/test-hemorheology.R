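# Time-series rheology: plateau selection, calibration, AI, viscosity
# series, stasis AI, summary metrics.

test_that("plateau selection finds the steady run", {
  expect_equal(plateau_velocity(rep(1.85, 40)), 1.85)

  # ramp over the first 10% then steady
  u <- c(seq(0, 2, length.out = 10), rep(1.85, 90))
  expect_equal(plateau_velocity(u), 1.85, tolerance = 1e-6)

  set.seed(3)
  noisy <- rnorm(60, 1, 0.2)   # CV ~ 20%
  expect_error(plateau_velocity(noisy), "no qualifying")
  expect_error(plateau_velocity(rep(1, 10)), "20 valid")
})

test_that("flow-rate calibration cancels multiplicative bias", {
  q <- calibrate_flow_rates(rep(1.85, 5), rep(0.0925, 5), 1.85, 0.4)
  expect_equal(q$q_mc, rep(0.4, 5))
  expect_equal(q$q_ac, rep(0.02, 5))
  # scaling all velocities by k leaves flow rates unchanged
  for (k in c(0.5, 3)) {
    qk <- calibrate_flow_rates(k * rep(1.85, 5), k * rep(0.0925, 5),
                               k * 1.85, 0.4)
    expect_equal(qk$q_mc, q$q_mc)
    expect_equal(qk$q_ac, q$q_ac)
  }
  expect_error(calibrate_flow_rates(1, 1, 0, 0.4), "positive")
})

test_that("aggregation index is the normalized intensity difference", {
  expect_equal(aggregation_index(100, 100), 0)
  expect_equal(aggregation_index(100, 80), 0.2)
  expect_warning(ai <- aggregation_index(c(100, 0), c(80, 10)), "non-positive")
  expect_true(is.na(ai[2]))
  expect_equal(ai[1], 0.2)
})

test_that("viscosity series applies the coflow model per trigger", {
  n <- 5
  vs <- viscosity_series(rep(0.5, n), q_mc = rep(0.4, n), q_ac = rep(0.03, n),
                         q_r = 0.37, mu_r = 1)
  expect_equal(vs$mu_b, rep(0.9185, n))
  expect_equal(vs$shear[1], shear_rate_viscosity_channel(0.4, 0.03, 0.5, 1, 0.05))

  # monotone interface -> monotone viscosity
  a <- seq(0.3, 0.8, length.out = 10)
  vs2 <- viscosity_series(a, rep(0.4, 10), rep(0.03, 10), 1.8, 1)
  expect_true(all(diff(vs2$mu_b) > 0))

  # invalid triggers propagate as NA, never as errors
  vs3 <- viscosity_series(c(0.5, NA, 0.99, 0.5), rep(0.4, 4),
                          c(0.03, 0.03, 0.03, 0.5), 1.8, 1)
  expect_true(is.na(vs3$mu_b[2]))  # missing interface
  expect_true(is.na(vs3$mu_b[3]))  # outside Cf domain
  expect_true(is.na(vs3$mu_b[4]))  # q_mc <= q_ac
  expect_false(is.na(vs3$mu_b[1]))
})

test_that("stasis AI is the fractional intensity decay after stopping", {
  t <- 0:130
  expect_equal(stasis_ai(t, rep(140, 131), t_stop = 0), 0)
  trace <- ifelse(t <= 4, 100, 100 - 20 * (t - 4) / 116)  # 100 -> 80 at 120 s
  expect_equal(stasis_ai(t, trace, t_stop = 0, duration = 120), 0.2)
  expect_error(stasis_ai(0:60, rep(1, 61), 0, 120), "cover")
})

test_that("AI_max smooths before taking the maximum", {
  expect_equal(ai_max(rep(0.2, 30)), 0.2)
  ai <- rep(0.2, 30); ai[15] <- 0.9
  # oracle: direct moving average
  sm <- vapply(1:30, function(i) mean(ai[max(1, i - 5):min(30, i + 5)]),
               numeric(1))
  expect_equal(ai_max(ai, 11), max(sm))
  expect_lt(ai_max(ai, 11), 0.9)
  expect_equal(ai_max(ai, 1), 0.9)
  expect_error(ai_max(c(NA_real_, NA_real_)), "valid")
})

test_that("normalized difference and COV match their definitions", {
  expect_equal(normalized_difference(1, 1), 0)
  expect_equal(normalized_difference(1.2, 1.0), 20)
  expect_equal(normalized_difference(2.33, 2.569), 9.3032, tolerance = 1e-4)
  expect_error(normalized_difference(1, 0), "zero")

  d <- 0.004 / sqrt(2)
  expect_equal(coefficient_of_variation(c(0.485 - d, 0.485 + d)),
               0.004 / 0.485 * 100, tolerance = 1e-10)
  expect_equal(round(coefficient_of_variation(c(0.485 - d, 0.485 + d)), 2),
               0.82)
  expect_equal(coefficient_of_variation(rep(2, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2 * 100,
               tolerance = 1e-10)
  expect_error(coefficient_of_variation(1), "2 values")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("linear fits recover slopes, origin constraint, R^2 conventions", {
  x <- 1:10
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  u_ac <- seq(0.05, 0.5, length.out = 8)
  f2 <- linear_fit(u_ac, 13.667 * u_ac, through_origin = TRUE)
  expect_equal(f2$slope, 13.667)
  expect_equal(100 / f2$slope, 7.317, tolerance = 1e-3)

  f3 <- linear_fit(x, rep(5, 10))
  expect_equal(f3$slope, 0)
  expect_equal(f3$r_squared, 0)
  expect_true(f3$degenerate)

  expect_error(linear_fit(rep(1, 5), 1:5), "variance")
})
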