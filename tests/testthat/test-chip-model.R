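# Closed-form chip physics: resistances, correction factor, the coflow
# viscosity model and its inverse, shear rates, flow split, transit time.

test_that("rectangular channel resistance scales correctly", {
  r1 <- rectangular_channel_resistance(14.5, 1, 0.05, 1)
  expect_equal(rectangular_channel_resistance(14.5, 1, 0.05, 2), 2 * r1)
  expect_equal(rectangular_channel_resistance(29, 1, 0.05, 1), 2 * r1)

  # narrow segment beats the long wide one; ratio from the formula itself
  r_narrow <- rectangular_channel_resistance(8.8, 0.1, 0.05, 1)
  expected_ratio <- (8.8 / 14.5) / 0.1 *
    (1 - 0.63 * 0.05 / 1) / (1 - 0.63 * 0.05 / 0.1)
  expect_gt(r_narrow, r1)
  expect_equal(r_narrow / r1, expected_ratio, tolerance = 1e-12)

  # wide-channel limit: aspect correction vanishes
  expect_equal(rectangular_channel_resistance(10, 1e6, 0.05, 1),
               12 * 1 * 10 / (1e6 * 0.05^3), tolerance = 1e-6)

  expect_error(rectangular_channel_resistance(-1, 1, 0.05, 1), "positive")
  expect_error(rectangular_channel_resistance(1, 0.04, 0.05, 1), "depth")
})

test_that("correction factor matches the calibrated quartic", {
  expect_equal(correction_factor(0, relax_domain = TRUE), 0.014)
  expect_equal(correction_factor(0.5), 0.9185)
  expect_equal(correction_factor(1, relax_domain = TRUE),
               -12.038 + 26.171 - 20.770 + 7.156 + 0.014)
  expect_error(correction_factor(0.97), "domain")
  expect_error(correction_factor(0.01), "0.05")
})

test_that("coflow viscosity model evaluates and scales as expected", {
  # identical fluids in symmetric coflow: Cf forced to 1
  unit_cf <- cf_model(coefficients = c(0, 0, 0, 0, 1))
  expect_equal(blood_viscosity(0.5, q_r = 0.37, q_b = 0.4, q_ac = 0.03,
                               mu_r = 1.3, model = unit_cf), 1.3)
  # direct evaluation with the calibrated Cf
  expect_equal(blood_viscosity(0.5, 1.8, 0.4, 0.03, 1),
               (1.8 / 0.37) * 0.9185, tolerance = 1e-12)
  # linear in mu_r
  expect_equal(blood_viscosity(0.5, 1.8, 0.4, 0.03, 2),
               2 * blood_viscosity(0.5, 1.8, 0.4, 0.03, 1))
  expect_error(blood_viscosity(0.5, 1.8, 0.4, 0.5, 1), "degenerate")
  expect_error(blood_viscosity(0.99, 1.8, 0.4, 0.03, 1), "domain")
})

test_that("interface inverse agrees with an independent root finder", {
  # oracle: uniroot on the same monotone map
  g <- function(a) a / (1 - a) * correction_factor(a)
  oracle <- uniroot(function(a) g(a) - 1, c(0.05, 0.95), tol = 1e-12)$root
  got <- interface_from_viscosity(1, 1, 1, 1)
  expect_equal(got, oracle, tolerance = 1e-7)
  expect_equal(round(got, 3), 0.521)

  # strictly increasing in mu_b
  alphas <- vapply(c(1, 2, 4, 8), function(m)
    interface_from_viscosity(m, 1, 2.5, 1), numeric(1))
  expect_true(all(diff(alphas) > 0))

  expect_error(interface_from_viscosity(100, 1, 0.1, 1), "unreachable")
})

test_that("viscosity <-> interface round trip is tight across the domain", {
  for (mu in c(0.3, 1, 2, 5, 12, 20)) {
    a <- tryCatch(interface_from_viscosity(mu, 1, 2.5, 0.95),
                  error = function(e) NA)
    if (is.na(a)) next
    back <- blood_viscosity(a, 2.5, 1, 0.05, 1)
    expect_equal(back, mu, tolerance = 1e-9)
  }
  # and the map g is strictly increasing over a dense grid
  a <- seq(0.05, 0.95, by = 1e-3)
  g <- a / (1 - a) * correction_factor(a)
  expect_true(all(diff(g) > 0))
})

test_that("shear-rate formulas reproduce the reference operating point", {
  expect_equal(shear_rate_rect(0.4, 1, 0.05), 266.6667, tolerance = 2e-4)
  expect_equal(shear_rate_rect(0.4, 0.1, 0.05), 2666.667, tolerance = 2e-4)
  expect_equal(shear_rate_rect(0, 1, 0.05), 0)
  expect_error(shear_rate_rect(0.4, 0, 0.05), "positive")

  expect_equal(shear_rate_viscosity_channel(0.4, 0, 1, 1, 0.05),
               shear_rate_rect(0.4, 1, 0.05))
  expect_equal(shear_rate_viscosity_channel(0.4, 0, 0.5, 1, 0.05),
               2 * shear_rate_rect(0.4, 1, 0.05))
  expect_equal(shear_rate_viscosity_channel(0.4, 0.03, 0.485, 1, 0.05),
               508.591, tolerance = 1e-5)
  expect_error(shear_rate_viscosity_channel(0.4, 0, 0, 1, 0.05), "alpha_b")
})

test_that("flow split conserves flow and honors branch resistances", {
  s <- flow_split(0.4)
  expect_identical(s$q_ac + s$q_vc, 0.4)
  expect_equal(s$q_ac / 0.4, 0.05)
  expect_identical(flow_split(0)$q_ac, 0)

  seg <- data.frame(length = 5, width = 0.1, depth = 0.05)
  g <- chip_geometry(segments_ac = seg, segments_vc = seg)
  s2 <- flow_split(1, g)
  expect_equal(s2$q_ac, 0.5)
  expect_equal(s2$q_ac + s2$q_vc, 1)
})

test_that("flow state enforces conservation", {
  fs <- flow_state(q_b = 0.4, q_r = 1.8, q_ac = 0.02)
  expect_equal(fs$q_vc, 0.38)
  expect_error(flow_state(0.4, 1.8, q_ac = 0.5))
})

test_that("tubing transit time matches plug-flow volume over rate", {
  t1 <- transit_time(0.25, 300, 0.4)
  expect_equal(t1, pi * 0.125^2 * 300 / (0.4 * 1000 / 3600), tolerance = 1e-12)
  expect_lt(abs(t1 - 132.5), 0.1)
  expect_equal(transit_time(0.25, 300, 0.8), t1 / 2)
  expect_equal(transit_time(0.25, 0, 0.4), 0)
  expect_error(transit_time(0.25, 300, 0), "positive")
})
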