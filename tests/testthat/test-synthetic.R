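# Synthetic-data generator: sedimentation law, phantom viscosity and
# aggregation deficit, burst rendering, and dataset determinism.

test_that("delivered hematocrit follows the sedimentation clock", {
  sc <- flow_scenario(duration = 100, seed = 1)
  bm0 <- blood_model(hct0 = 0.45, sed_amplitude = 0)
  expect_equal(delivered_hematocrit(c(0, 50, 100), sc, bm0),
               rep(0.45, 3))

  bm <- blood_model(hct0 = 0.45, sed_amplitude = 0.2, sed_tau = 600,
                    stasis_kappa = 6)
  expect_equal(delivered_hematocrit(0, sc, bm), 0.45)

  # a 20-min off period accelerates sedimentation vs the same elapsed time
  # delivered continuously; oracle: evaluate the clock analytically
  sc_off <- flow_scenario(duration = 1500, t_wait = 1200, seed = 1)
  sc_on <- flow_scenario(duration = 1500, seed = 1)
  t <- 1500
  s_off <- 1200 * 6 + 300   # waiting accrues at kappa = 6
  s_on <- 1500
  expect_equal(delivered_hematocrit(t, sc_off, bm),
               min(0.45 * (1 + 0.2 * (1 - exp(-s_off / 600))), 0.8),
               tolerance = 1e-8)
  expect_equal(delivered_hematocrit(t, sc_on, bm),
               0.45 * (1 + 0.2 * (1 - exp(-s_on / 600))), tolerance = 1e-8)
  expect_gt(delivered_hematocrit(t, sc_off, bm),
            delivered_hematocrit(t, sc_on, bm))
})

test_that("phantom viscosity is the medium times a hematocrit factor", {
  bm <- blood_model(hct0 = 0.5, medium_slope = 0.03)
  expect_equal(phantom_viscosity(0, 20, bm), 1 + 0.03 * 20)
  expect_gt(phantom_viscosity(0.5, 10, bm), phantom_viscosity(0.3, 10, bm))
  expect_gt(phantom_viscosity(0.4, 20, bm), phantom_viscosity(0.4, 5, bm))
  expect_error(phantom_viscosity(0.99, 0, bm), "0.98")
  # Newtonian override wins
  bmf <- blood_model(hct0 = 0.05, fixed_viscosity = 2.569)
  expect_equal(phantom_viscosity(0.5, 20, bmf), 2.569)
})

test_that("aggregation deficit responds to aggregability, dextran, shear", {
  expect_equal(phantom_aggregation_deficit(0.5, 20, 0, 10), 0)
  expect_equal(phantom_aggregation_deficit(0.5, 0, 1, 10), 0)
  d <- vapply(c(5, 10, 15, 20), function(c)
    phantom_aggregation_deficit(0.5, c, 1, 10), numeric(1))
  expect_equal(which.max(d), 3L)  # peak at 15 mg/mL
  expect_true(all(d >= 0 & d <= 0.5))
  # decreasing in shear, decreasing in hematocrit
  expect_gt(phantom_aggregation_deficit(0.5, 15, 1, 5),
            phantom_aggregation_deficit(0.5, 15, 1, 500))
  expect_gt(phantom_aggregation_deficit(0.3, 15, 1, 10),
            phantom_aggregation_deficit(0.6, 15, 1, 10))
})

test_that("rendered bursts honor intensity, interface, and frozen flow", {
  g <- test_geometry()
  set.seed(5)
  st <- list(hct = 0, alpha_b = 0.485, u_mc = 2.2, u_ac = 0.11,
             deficit = 0, on = TRUE)
  sett <- render_settings(noise_sd = 0)
  burst <- render_burst(st, g, sett)

  # Hct 0, no deficit, no noise: everything at background except particles
  f1 <- burst[[1]]
  expect_equal(max(f1), sett$background)
  expect_gt(mean(f1 == sett$background), 0.4)

  # interface row: vc band has exactly round(0.485 * 200) sub-background rows
  vc_rows <- (g$roi_vc[1] + 1):g$roi_vc[2]
  st2 <- list(hct = 0.5, alpha_b = 0.485, u_mc = 2.2, u_ac = 0.11,
              deficit = 0, on = TRUE)
  b2 <- render_burst(st2, g, sett)
  dark <- rowSums(b2[[1]][vc_rows, ] < sett$background - 50) > 0
  expect_equal(sum(dark), round(0.485 * g$width_px))
  expect_true(all(which(dark) == seq_len(sum(dark))))  # contiguous from top

  # frames of a burst differ only where particles moved: the vc band and
  # everything outside the chambers is identical
  expect_equal(b2[[1]][vc_rows, ], b2[[2]][vc_rows, ])
  mask_rows <- setdiff(seq_len(g$frame_dim[1]),
                       c((g$roi_mc[1] + 1):g$roi_mc[2],
                         (g$roi_ac[1] + 1):g$roi_ac[2]))
  expect_equal(b2[[1]][mask_rows, ], b2[[2]][mask_rows, ])

  # oversized displacement triggers the aliasing warning
  st3 <- within(st2, u_mc <- 50)
  expect_warning(render_burst(st3, g, sett), "alias")
})

test_that("dataset generation is deterministic and tracks the model", {
  g <- test_geometry(roi_cols = 30)
  sc <- flow_scenario(q_b = 0.4, q_r = 2.5, duration = 6, seed = 99)
  bm <- blood_model(hct0 = 0.5, c_dex = 0, sed_amplitude = 0)
  sett <- render_settings()

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  r1 <- generate_dataset(sc, bm, g, sett, file.path(d1, "x.tiff"))
  r2 <- generate_dataset(sc, bm, g, sett, file.path(d2, "x.tiff"))
  expect_identical(unname(tools::md5sum(r1$tiff)), unname(tools::md5sum(r2$tiff)))
  expect_identical(readLines(r1$manifest), readLines(r2$manifest))

  # control blood: interface constant over time
  expect_equal(length(unique(r1$truth$alpha_b)), 1L)

  # sedimenting dextran blood: viscosity strictly increases
  bm2 <- blood_model(hct0 = 0.5, c_dex = 20, sed_amplitude = 0.15)
  sc2 <- flow_scenario(q_b = 0.4, q_r = 1.8, duration = 6, seed = 99)
  r3 <- generate_dataset(sc2, bm2, g, sett, file.path(d1, "y.tiff"))
  expect_true(all(diff(r3$truth$mu_b) > 0))
  expect_true(all(diff(r3$truth$alpha_b) > 0))

  # manifest round-trips through JSON
  m <- read_manifest(r3$manifest)
  expect_equal(m$triggers$mu_b, r3$truth$mu_b)
  expect_equal(m$seed, 99)

  # unreachable interface at absurd flow ratio errors with advice
  sc3 <- flow_scenario(q_b = 0.4, q_r = 1000, duration = 2, seed = 1)
  expect_error(generate_dataset(sc3, bm, g, sett, file.path(d1, "z.tiff")),
               "q_r|unreachable")
})

test_that("off-schedule triggers carry zero velocity in the manifest", {
  g <- test_geometry(roi_cols = 30)
  sc <- flow_scenario(q_b = 0.4, q_r = 2.5, duration = 8, t_wait = 3,
                      seed = 7)
  bm <- blood_model(hct0 = 0.5)
  r <- generate_dataset(sc, bm, g, render_settings(),
                        file.path(tempdir(), "off.tiff"))
  off <- r$truth$state == "off"
  expect_true(any(off) && any(!off))
  expect_true(all(r$truth$u_mc[off] == 0))
  expect_true(all(r$truth$u_mc[!off] > 0))
  expect_equal(schedule_state(c(0, 2.9, 3, 7.5), sc),
               c("off", "off", "on", "on"))
})
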