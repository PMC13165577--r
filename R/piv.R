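# Micro-PIV: windowed cross-correlation of within-burst frame pairs with
# subpixel Gaussian peak fitting, vector validation, and ROI averaging.
#
# The correlator is a two-stage scheme per interrogation window. Stage 1
# finds the integer displacement by minimizing the sum of squared
# differences (SSD) between the window and every in-bounds offset window of
# the second frame inside the search radius; SSD is computed from one
# zero-padded FFT correlation plus summed-area tables, is exactly zero for
# a pure translation, and (unlike plain correlation) is not fooled by
# bright particles just outside the window. Stage 2 re-extracts the second
# window at the integer offset and refines the residual by a three-point
# Gaussian fit on the zero-mean, overlap-normalized correlation of the
# matched windows. Windows whose offset content matches the first frame
# exactly return the integer vector untouched, so pure translations are
# recovered exactly. Search regions and offset windows are taken from the
# full frame, not the ROI, since matched image content advects in from
# outside the ROI.

#' Default interrogation window size for a pixel scale
#'
#' The physical interrogation window is 67 x 67 um^2; the pixel window is
#' the nearest odd pixel count at the given scale.
#'
#' @param pixel_scale Image scale (um/px).
#' @return Odd integer window size in px.
#' @export
piv_window_px <- function(pixel_scale) {
  w <- max(round(67 / pixel_scale), 3)
  if (w %% 2 == 0) w + 1 else w
}

# Three-point log-Gaussian subpixel fit (falls back to a parabolic fit when
# any sample is non-positive); returns offset in [-1, 1].
subpixel_fit <- function(cm1, c0, cp1) {
  if (cm1 > 0 && c0 > 0 && cp1 > 0) {
    den <- 2 * (log(cm1) + log(cp1) - 2 * log(c0))
    if (den < 0) return(max(min((log(cm1) - log(cp1)) / den, 1), -1))
  }
  den <- 2 * cm1 - 4 * c0 + 2 * cp1
  if (den < 0) return(max(min((cm1 - cp1) / den, 1), -1))
  0
}

#' Cross-correlate a frame pair over a window grid
#'
#' Tiles the ROI with interrogation windows at the requested overlap and
#' estimates one displacement vector per window. Flat (zero-variance)
#' windows are flagged invalid rather than guessed.
#'
#' @param frame_a,frame_b Numeric matrices of identical dimension
#'   (intensities; any consistent scale).
#' @param window_px Odd interrogation window size (px).
#' @param overlap Fractional window overlap in \[0, 0.9\].
#' @param roi Optional ROI rectangle `c(row0, row1, col0, col1)` (0-based,
#'   half-open); default is the whole frame.
#' @param max_disp Peak-search radius (px); default `window_px %/% 3`.
#' @return An object of class `velocity_field`: matrices `u` (column/flow
#'   direction, px per frame interval), `v` (row direction), `valid`, and
#'   the window center coordinates.
#' @export
cross_correlate_pair <- function(frame_a, frame_b, window_px = 13,
                                 overlap = 0.5, roi = NULL, max_disp = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("cross_correlate_pair: frames must have identical dimensions")
  stopifnot(window_px >= 3, overlap >= 0, overlap <= 0.9)
  if (is.null(roi)) roi <- c(0, nrow(frame_a), 0, ncol(frame_a))
  nr_roi <- roi[2] - roi[1]; nc_roi <- roi[4] - roi[3]
  w <- as.integer(window_px)
  if (w > nr_roi || w > nc_roi)
    stop("cross_correlate_pair: window does not fit in the ROI")
  if (is.null(max_disp)) max_disp <- w %/% 3
  step <- max(1L, as.integer(round(w * (1 - overlap))))

  m <- as.integer(max_disp)
  mext <- m + 1L                     # fit neighbors need one extra lag
  side <- w + 2L * mext
  pad <- 2^ceiling(log2(side))

  # candidate integer displacements (search radius m) and the index of each
  # lag k in the correlation array (template placed at origin, region offset
  # by mext): lag k lives at wrapped index k + mext
  cand <- as.matrix(expand.grid(kr = -m:m, kc = -m:m))
  lag_idx <- function(kr, kc) cbind(((kr + mext) %% pad) + 1L,
                                    ((kc + mext) %% pad) + 1L)
  idx_c <- lag_idx(cand[, 1], cand[, 2])
  off <- cand + mext                 # 0-based offsets into the region

  # overlap-normalized zero-mean correlation of two matched w x w windows,
  # used for the subpixel fit (precise to a few hundredths of a pixel at
  # sub-pixel displacements)
  lags <- 0:(pad - 1); lags[lags > pad / 2] <- lags[lags > pad / 2] - pad
  ovc <- pmax(outer(pmax(w - abs(lags), 0), pmax(w - abs(lags), 0)), 1)
  mask_full <- abs(outer(lags, rep(1, pad))) <= m &
    abs(outer(rep(1, pad), lags)) <= m
  wrap <- function(i) ((i - 1) %% pad) + 1
  surf <- function(a, b) {
    ap <- matrix(0, pad, pad); bp <- matrix(0, pad, pad)
    ap[1:w, 1:w] <- a; bp[1:w, 1:w] <- b
    C <- Re(stats::fft(stats::fft(bp) * Conj(stats::fft(ap)), inverse = TRUE)) /
      (pad * pad)
    C / ovc
  }
  peak_fit <- function(Cn) {
    Cm <- Cn; Cm[!mask_full] <- -Inf
    pk <- which(Cm == max(Cm), arr.ind = TRUE)[1, ]
    dr <- subpixel_fit(Cn[wrap(pk[1] - 1), pk[2]], Cn[pk[1], pk[2]],
                       Cn[wrap(pk[1] + 1), pk[2]])
    dc <- subpixel_fit(Cn[pk[1], wrap(pk[2] - 1)], Cn[pk[1], pk[2]],
                       Cn[pk[1], wrap(pk[2] + 1)])
    c(lags[pk[1]], lags[pk[2]], dr, dc)
  }

  row_starts <- seq(roi[1] + 1, roi[2] - w + 1, by = step)
  col_starts <- seq(roi[3] + 1, roi[4] - w + 1, by = step)
  u <- v <- matrix(NA_real_, length(row_starts), length(col_starts))
  valid <- matrix(FALSE, length(row_starts), length(col_starts))
  nr <- nrow(frame_a); nc <- ncol(frame_a)

  for (ri in seq_along(row_starts)) for (ci in seq_along(col_starts)) {
    r0 <- row_starts[ri]; c0 <- col_starts[ci]
    a_raw <- frame_a[r0:(r0 + w - 1), c0:(c0 + w - 1)]
    b_raw <- frame_b[r0:(r0 + w - 1), c0:(c0 + w - 1)]
    if (stats::sd(a_raw) == 0 || stats::sd(b_raw) == 0) next

    # raw full-support template correlation of the window against a
    # (w + 2 mext)-sided search region of frame B (zero outside the frame)
    reg <- matrix(0, side, side)
    rr <- (r0 - mext):(r0 + w - 1 + mext); cc <- (c0 - mext):(c0 + w - 1 + mext)
    rok <- rr >= 1 & rr <= nr; cok <- cc >= 1 & cc <= nc
    reg[rok, cok] <- frame_b[rr[rok], cc[cok]]
    ap <- matrix(0, pad, pad); bp <- matrix(0, pad, pad)
    ap[1:w, 1:w] <- a_raw; bp[1:side, 1:side] <- reg
    craw <- Re(stats::fft(stats::fft(bp) * Conj(stats::fft(ap)),
                          inverse = TRUE)) / (pad * pad)

    # sliding w x w sums of the region and its square via summed-area tables
    sat <- rbind(0, cbind(0, t(apply(apply(reg^2, 2, cumsum), 1, cumsum))))
    win_sum <- function(sat, i0, j0)
      sat[cbind(i0 + w + 1, j0 + w + 1)] - sat[cbind(i0 + 1, j0 + w + 1)] -
      sat[cbind(i0 + w + 1, j0 + 1)] + sat[cbind(i0 + 1, j0 + 1)]

    # integer stage: minimize the sum of squared differences over in-bounds
    # offsets. SSD is exactly zero at a pure translation and its energy term
    # penalizes the spurious high-energy alignments that plain correlation
    # can prefer when a bright particle sits just outside the window.
    e_a <- sum(a_raw^2)
    ssd <- e_a + win_sum(sat, off[, 1], off[, 2]) - 2 * craw[idx_c]
    in_bounds <- r0 + cand[, 1] >= 1 & c0 + cand[, 2] >= 1 &
      r0 + cand[, 1] + w - 1 <= nr & c0 + cand[, 2] + w - 1 <= nc
    ssd[!in_bounds] <- Inf
    best <- order(ssd, abs(cand[, 1]) + abs(cand[, 2]))[1]
    kr <- cand[best, 1]; kc <- cand[best, 2]

    b2_raw <- frame_b[(r0 + kr):(r0 + kr + w - 1), (c0 + kc):(c0 + kc + w - 1)]
    if (isTRUE(all(b2_raw == a_raw))) {
      # pure translation: exact integer vector
      v[ri, ci] <- kr; u[ri, ci] <- kc; valid[ri, ci] <- TRUE
      next
    }

    # subpixel stage: three-point Gaussian fit on the zero-mean
    # overlap-normalized correlation of the window with the offset window,
    # at that surface's own peak (usually the center)
    if (stats::sd(b2_raw) == 0) next
    p2 <- peak_fit(surf(a_raw - mean(a_raw), b2_raw - mean(b2_raw)))
    v[ri, ci] <- kr + p2[1] + p2[3]
    u[ri, ci] <- kc + p2[2] + p2[4]
    valid[ri, ci] <- TRUE
  }
  structure(list(u = u, v = v, valid = valid,
                 centers_row = row_starts - 1 + (w - 1) / 2,
                 centers_col = col_starts - 1 + (w - 1) / 2,
                 window_px = w, step_px = step),
            class = "velocity_field")
}

#' Validate displacement vectors
#'
#' Two filters, applied to both components: a local filter invalidating a
#' vector whose deviation from its 3x3 neighborhood median exceeds
#' `median_threshold * (neighborhood residual scale + eps)`, and a global
#' filter invalidating vectors outside `mean +/- std_threshold * SD`.
#' Fields too small for a neighborhood fall back to the global filter only.
#' Invalid vectors are flagged, never replaced.
#'
#' @param field A `velocity_field`.
#' @param median_threshold Local median filter multiplier.
#' @param std_threshold Global standard-deviation filter multiplier.
#' @param eps Residual-scale floor (px), stabilizing the local filter on
#'   uniform flow.
#' @return The field with updated `valid` flags.
#' @export
validate_vectors <- function(field, median_threshold = 2, std_threshold = 3,
                             eps = 0.1) {
  stopifnot(inherits(field, "velocity_field"))
  if (!any(field$valid)) stop("validate_vectors: empty field")
  nr <- nrow(field$u); nc <- ncol(field$u)
  keep <- field$valid

  if (nr >= 2 && nc >= 2 && sum(field$valid) >= 3) {
    for (comp in c("u", "v")) {
      x <- field[[comp]]
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!field$valid[i, j]) next
        ri <- max(1, i - 1):min(nr, i + 1)
        ci <- max(1, j - 1):min(nc, j + 1)
        nb <- x[ri, ci]
        center <- which(ri == i) + (which(ci == j) - 1L) * length(ri)
        nb <- nb[-center]
        nb <- nb[!is.na(nb)]
        if (length(nb) < 3) next
        med <- stats::median(nb)
        scale <- stats::median(abs(nb - med))
        if (abs(x[i, j] - med) > median_threshold * (scale + eps))
          keep[i, j] <- FALSE
      }
    }
  }
  for (comp in c("u", "v")) {
    x <- field[[comp]][field$valid]
    if (length(x) >= 2) {
      mu <- mean(x); sdev <- stats::sd(x)
      if (sdev > 0) {
        out <- abs(field[[comp]] - mu) > std_threshold * sdev
        keep[which(out & field$valid)] <- FALSE
      }
    }
  }
  if (!any(keep)) stop("validate_vectors: all vectors invalidated")
  field$valid <- keep
  field
}

#' ROI-averaged speed in mm/s
#'
#' Averages the valid vectors over the ROI and converts from px per frame
#' interval to mm/s. The default (`average = "vector"`) takes the magnitude
#' of the component-wise mean vector, appropriate for the uniform
#' unidirectional chamber flows measured here: near-zero displacements stay
#' unbiased because zero-mean estimation noise cancels instead of being
#' rectified. `average = "magnitude"` takes the mean of the per-vector
#' magnitudes instead (positively biased when the displacement is small
#' relative to the noise).
#'
#' @param field A `velocity_field` (already computed over the ROI).
#' @param pixel_scale Image scale (um/px).
#' @param dt Frame interval (s).
#' @param average `"vector"` or `"magnitude"` (see above).
#' @return Speed in mm/s, or `NA` (with a warning) if no vector is valid.
#' @export
roi_mean_velocity <- function(field, pixel_scale, dt,
                              average = c("vector", "magnitude")) {
  stopifnot(inherits(field, "velocity_field"), pixel_scale > 0, dt > 0)
  average <- match.arg(average)
  if (!any(field$valid)) {
    warning("roi_mean_velocity: no valid vectors; returning NA")
    return(NA_real_)
  }
  mag <- if (average == "vector") {
    sqrt(mean(field$u[field$valid])^2 + mean(field$v[field$valid])^2)
  } else {
    mean(sqrt(field$u^2 + field$v^2)[field$valid])
  }
  mag * pixel_scale / 1000 / dt
}
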