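# Shared fixtures: a small chip geometry for fast closed-loop runs, a
# particle-image renderer for PIV unit tests, and brute-force oracles.

# Small geometry: full 1-mm channel width (200 px at 5 um/px) but short
# 0.3-mm ROIs, so closed-loop runs stay fast.
test_geom_args <- function(roi_cols = 60) {
  list(pixel_scale = 5,
       frame_dim = c(660, roi_cols + 40),
       roi_mc = c(10, 210, 20, 20 + roi_cols),
       roi_ac = c(230, 430, 20, 20 + roi_cols),
       roi_vc = c(450, 650, 20, 20 + roi_cols))
}

test_geometry <- function(roi_cols = 60) {
  do.call(chip_geometry, test_geom_args(roi_cols))
}

# Analytic Gaussian particle frame: particles at continuous (row, col)
# positions, optionally shifted; 8-bit quantized like the real renderer.
particle_frame <- function(nr, nc, pos, dy = 0, dx = 0, bg = 120, amp = 50,
                           sigma = 1, noise = 0) {
  f <- matrix(bg, nr, nc)
  r3 <- ceiling(3 * sigma) + 1
  for (i in seq_len(nrow(pos))) {
    pr <- pos[i, 1] + dy; pc <- pos[i, 2] + dx
    if (pr < 1 - r3 || pr > nr + r3 || pc < 1 - r3 || pc > nc + r3) next
    rr <- max(1, floor(pr) - r3):min(nr, ceiling(pr) + r3)
    cc <- max(1, floor(pc) - r3):min(nc, ceiling(pc) + r3)
    g <- outer(exp(-(rr - pr)^2 / (2 * sigma^2)),
               exp(-(cc - pc)^2 / (2 * sigma^2)))
    f[rr, cc] <- f[rr, cc] - amp * g
  }
  if (noise > 0) f <- f + matrix(rnorm(nr * nc, 0, noise), nr, nc)
  pmax(pmin(round(f), 255), 0)
}

random_particles <- function(n, nr, nc, margin = 8) {
  cbind(runif(n, 1 - margin, nr + margin), runif(n, 1 - margin, nc + margin))
}

# Brute-force Otsu oracle: scan every candidate threshold and compute the
# between-class variance directly from the pixel values.
otsu_bruteforce <- function(pixels) {
  px <- pmax(pmin(round(as.numeric(pixels)), 255), 0)
  n <- length(px)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (!length(lo) || !length(hi)) v <- 0
    else {
      w0 <- length(lo) / n
      v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Hand-built velocity field for unit tests of validation/averaging.
make_field <- function(u, v = u * 0, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(u)
  structure(list(u = u, v = v, valid = valid,
                 centers_row = seq_len(nrow(u)), centers_col = seq_len(ncol(u)),
                 window_px = 13L, step_px = 6L),
            class = "velocity_field")
}
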