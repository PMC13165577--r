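# Converts per-trigger channel measurements into calibrated flow rates,
# viscosity, shear rate and aggregation indices, plus the summary metrics
# used to compare runs (plateau velocity, AI_max, COV, ND, linear fits).

#' Steady plateau velocity
#'
#' Mean of the series over the longest contiguous run in which the rolling
#' coefficient of variation stays below `cv_threshold`. The rolling window
#' is `window_frac` of the series length; a qualifying run must cover at
#' least `min_run_frac` of the samples. Ties between equally long runs go
#' to the earliest.
#'
#' @param u Velocity series (mm/s); `NA`s are non-qualifying.
#' @param window_frac Rolling-CV window as a fraction of the series length.
#' @param cv_threshold Maximum rolling CV (fraction, default 5%).
#' @param min_run_frac Minimum qualifying run length as a fraction.
#' @return The plateau velocity.
#' @export
plateau_velocity <- function(u, window_frac = 0.1, cv_threshold = 0.05,
                             min_run_frac = 0.1) {
  n_valid <- sum(!is.na(u))
  if (n_valid < 20)
    stop("plateau_velocity: need at least 20 valid samples")
  n <- length(u)
  win <- max(3L, as.integer(round(window_frac * n)))
  half <- win %/% 2
  cv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    seg <- u[max(1, i - half):min(n, i + half)]
    seg <- seg[!is.na(seg)]
    if (length(seg) >= 3 && mean(seg) > 0)
      cv[i] <- stats::sd(seg) / mean(seg)
  }
  ok <- !is.na(u) & !is.na(cv) & cv < cv_threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  good <- which(r$values)
  if (length(good)) {
    lens <- r$lengths[good]
    best <- good[which.max(lens)]   # first of the longest runs
    if (r$lengths[best] >= max(2, min_run_frac * n)) {
      idx <- starts[best]:ends[best]
      return(mean(u[idx], na.rm = TRUE))
    }
  }
  stop("plateau_velocity: no qualifying steady run; select the averaging ",
       "window manually")
}

#' Calibrate flow rates from velocities
#'
#' `Q_mc = U_mc / <U_mc> * Q_b` and `Q_ac = U_ac / <U_mc> * Q_b`: scaling
#' by the plateau velocity cancels any multiplicative velocimetry bias.
#'
#' @param u_mc,u_ac Velocity series (mm/s).
#' @param u_plateau Plateau velocity `<U_mc>` (mm/s), positive.
#' @param q_b Set delivery flow rate (mL/h).
#' @return List with `q_mc` and `q_ac` series (mL/h).
#' @export
calibrate_flow_rates <- function(u_mc, u_ac, u_plateau, q_b) {
  if (!is.finite(u_plateau) || u_plateau <= 0)
    stop("calibrate_flow_rates: plateau velocity must be positive")
  stopifnot(q_b > 0)
  list(q_mc = u_mc / u_plateau * q_b,
       q_ac = u_ac / u_plateau * q_b)
}

#' RBC aggregation index
#'
#' `AI = (I_mc - I_ac) / I_mc` per trigger. Computed on raw intensities by
#' default (background-subtracted intensities can drive `I_mc` toward zero
#' and destabilize the ratio); non-positive `I_mc` yields `NA` with a
#' warning rather than a fabricated value.
#'
#' @param i_mc,i_ac Mean chamber intensity series.
#' @return AI series.
#' @export
aggregation_index <- function(i_mc, i_ac) {
  ai <- (i_mc - i_ac) / i_mc
  bad <- !is.na(i_mc) & i_mc <= 0
  if (any(bad)) {
    warning("aggregation_index: non-positive I_mc at ", sum(bad),
            " trigger(s); AI undefined there")
    ai[bad] <- NA_real_
  }
  ai
}

#' Per-trigger viscosity and shear-rate series
#'
#' Applies the coflowing-stream viscosity model per trigger with the
#' calibrated `Q_mc - Q_ac` as the blood flow rate, and the blood-stream
#' shear-rate formula on the same quantities. Triggers with missing or
#' out-of-domain inputs yield `NA` rather than errors.
#'
#' @param alpha_b Interface series.
#' @param q_mc,q_ac Calibrated flow-rate series (mL/h).
#' @param q_r Reference-fluid flow rate (mL/h).
#' @param mu_r Reference-fluid viscosity (cP).
#' @param geometry A [chip_geometry()].
#' @param model A [cf_model()].
#' @return List with `mu_b` (cP) and `shear` (1/s) series.
#' @export
viscosity_series <- function(alpha_b, q_mc, q_ac, q_r, mu_r,
                             geometry = chip_geometry(), model = cf_model()) {
  n <- length(alpha_b)
  stopifnot(length(q_mc) == n, length(q_ac) == n)
  mu <- shear <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- alpha_b[i]; qm <- q_mc[i]; qa <- q_ac[i]
    if (is.na(a) || is.na(qm) || is.na(qa)) next
    if (a < model$domain[1] || a > model$domain[2]) next
    if (qm - qa <= 0) next
    mu[i] <- blood_viscosity(a, q_r, qm, qa, mu_r, model)
    shear[i] <- shear_rate_viscosity_channel(qm, qa, a,
                                             geometry$width, geometry$depth)
  }
  list(mu_b = mu, shear = shear)
}

#' Conventional stopped-flow (stasis) aggregation index
#'
#' Endpoint-ratio variant of the classical syllectometric index:
#' `AI = (I(t_stop) - I(t_stop + duration)) / I(t_stop)` where `I(t_stop)`
#' is the mean of the first 5 samples after the stop and the end value is
#' the last sample within the window.
#'
#' @param t Sample times (s).
#' @param intensity Intensity trace.
#' @param t_stop Flow stop time (s).
#' @param duration Observation window after the stop (s).
#' @return The stasis aggregation index.
#' @export
stasis_ai <- function(t, intensity, t_stop, duration = 120) {
  stopifnot(length(t) == length(intensity))
  after <- which(t >= t_stop)
  if (length(after) < 5 || max(t) < t_stop + duration)
    stop("stasis_ai: trace must cover [t_stop, t_stop + duration]")
  i0 <- mean(intensity[after[1:5]])
  iend <- intensity[max(which(t <= t_stop + duration))]
  (i0 - iend) / i0
}

#' Maximum of the smoothed aggregation-index series
#'
#' Moving-average smoothing (odd window, truncated at the edges) followed
#' by the maximum; `smooth_window = 1` gives the plain maximum.
#'
#' @param ai AI series (may contain `NA`).
#' @param smooth_window Odd smoothing window length (triggers).
#' @return `AI_max`.
#' @export
ai_max <- function(ai, smooth_window = 11) {
  if (all(is.na(ai))) stop("ai_max: no valid AI values")
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  n <- length(ai)
  half <- smooth_window %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(ai[max(1, i - half):min(n, i + half)], na.rm = TRUE), numeric(1))
  max(sm, na.rm = TRUE)
}

#' Normalized difference (percent)
#'
#' `ND = |measured - expected| / |expected| * 100`, the field-standard
#' accuracy metric against a theoretical value.
#'
#' @param measured,expected Numeric values; `expected` non-zero.
#' @return ND in percent.
#' @export
normalized_difference <- function(measured, expected) {
  if (any(expected == 0)) stop("normalized_difference: expected value is zero")
  abs(measured - expected) / abs(expected) * 100
}

#' Coefficient of variation (percent)
#'
#' @param x Numeric series, `n >= 2`, non-zero mean.
#' @return `sd(x) / mean(x) * 100`.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("coefficient_of_variation: need at least 2 values")
  m <- mean(x)
  if (m == 0) stop("coefficient_of_variation: zero mean")
  stats::sd(x) / m * 100
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors.
#' @param through_origin Constrain the intercept to zero.
#' @return List with `slope`, `intercept`, `r_squared`, and
#'   `degenerate` (TRUE when `y` is constant so that SStot = 0; the
#'   convention then reports R^2 = 0).
#' @export
linear_fit <- function(x, y, through_origin = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (!through_origin && stats::var(x) == 0)
    stop("linear_fit: zero variance in x")
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- if (through_origin) unname(co[1]) else unname(co[2])
  intercept <- if (through_origin) 0 else unname(co[1])
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2,
       degenerate = degenerate)
}
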