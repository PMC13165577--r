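# Micro-PIV correlator: exactness on integer translations, subpixel
# accuracy on fractional shifts, vector validation, ROI averaging.

test_that("integer translations are recovered exactly", {
  set.seed(42)
  pos <- random_particles(1100, 120, 160)
  a <- particle_frame(120, 160, pos)
  b <- particle_frame(120, 160, pos, dy = 1, dx = 3)
  fld <- cross_correlate_pair(a, b, 13, 0.5, roi = c(20, 100, 20, 140))
  expect_true(all(fld$valid))
  expect_equal(max(abs(fld$u - 3)), 0, tolerance = 1e-10)
  expect_equal(max(abs(fld$v - 1)), 0, tolerance = 1e-10)
})

test_that("zero shift gives identically zero vectors", {
  set.seed(43)
  pos <- random_particles(300, 100, 100)
  a <- particle_frame(100, 100, pos)
  fld <- cross_correlate_pair(a, a, 13, 0.5)
  expect_equal(max(abs(fld$u)), 0, tolerance = 1e-10)
  expect_equal(max(abs(fld$v)), 0, tolerance = 1e-10)
})

test_that("fractional shifts are recovered to better than 0.1 px", {
  for (d in c(0.5, 2.5)) {
    set.seed(100 + round(10 * d))
    pos <- random_particles(1200, 200, 160)
    a <- particle_frame(200, 160, pos)
    b <- particle_frame(200, 160, pos, dx = d)
    fld <- cross_correlate_pair(a, b, 13, 0.5, roi = c(10, 190, 10, 150))
    fld <- validate_vectors(fld)
    expect_lt(abs(mean(fld$u[fld$valid]) - d), 0.1)
    expect_lt(abs(mean(fld$v[fld$valid])), 0.05)
  }
})

test_that("flat windows are flagged invalid, not guessed", {
  set.seed(44)
  a <- matrix(120, 80, 80)
  pos <- random_particles(80, 40, 80, margin = 0)  # texture only in top half
  a[1:40, ] <- particle_frame(40, 80, pos)
  b <- a
  fld <- cross_correlate_pair(a, b, 13, 0.5)
  expect_true(any(fld$valid))
  expect_true(any(!fld$valid))   # flat bottom half
  expect_true(all(is.na(fld$u[!fld$valid])))
})

test_that("vector validation flags spikes and respects degenerate fields", {
  u <- matrix(2, 5, 5)
  fld <- validate_vectors(make_field(u))
  expect_true(all(fld$valid))    # uniform field untouched

  u2 <- u; u2[3, 3] <- 20
  fld2 <- validate_vectors(make_field(u2))
  expect_false(fld2$valid[3, 3])
  expect_equal(sum(!fld2$valid), 1L)

  # two-vector field: only the global filter applies, nothing invalidated
  u3 <- matrix(c(1, 1.2), 1, 2)
  fld3 <- validate_vectors(make_field(u3))
  expect_true(all(fld3$valid))

  expect_error(validate_vectors(make_field(matrix(NA_real_, 2, 2))), "empty")
})

test_that("ROI mean velocity converts units and skips invalid vectors", {
  u <- matrix(2, 4, 4); v <- matrix(0, 4, 4)
  expect_equal(roi_mean_velocity(make_field(u, v), pixel_scale = 5, dt = 1e-3),
               10)
  # half the vectors invalid at a different value: only valid half counts
  u2 <- u; u2[1:2, ] <- 100
  valid <- matrix(TRUE, 4, 4); valid[1:2, ] <- FALSE
  expect_equal(roi_mean_velocity(make_field(u2, v, valid), 5, 1e-3), 10)
  # none valid: NA with warning
  expect_warning(
    r <- roi_mean_velocity(make_field(u, v, valid & FALSE), 5, 1e-3), "NA")
  expect_true(is.na(r))
})

test_that("chamber-speed recovery is within 5% at the working displacement", {
  # 1.85 mm/s at 5 um/px and 1 ms -> 0.37 px/frame
  set.seed(46)
  d <- 1.85 * 1e-3 * 1000 / 5
  pos <- random_particles(1200, 200, 160)
  a <- particle_frame(200, 160, pos)
  b <- particle_frame(200, 160, pos, dx = d)
  fld <- validate_vectors(cross_correlate_pair(a, b, 13, 0.5,
                                               roi = c(10, 190, 10, 150)))
  u <- roi_mean_velocity(fld, pixel_scale = 5, dt = 1e-3)
  expect_lt(abs(u - 1.85) / 1.85, 0.05)
})
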