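# Closed-form physics of the three-channel chip: hydraulic resistances, the
# coflowing-stream viscosity model with its empirical correction factor,
# shear-rate formulas, the flow split at the aggregation-channel junction,
# and tubing transit time.
#
# Canonical internal units: mm, s, mm^3/s, cP. Flow rates are accepted in
# mL/h at every public boundary and converted once.

#' Convert a flow rate from mL/h to mm^3/s
#'
#' @param q_mlh Flow rate in mL/h.
#' @return Flow rate in mm^3/s (1 mL/h = 1000/3600 mm^3/s).
#' @export
mlh_to_mm3s <- function(q_mlh) q_mlh * (1000 / 3600)

#' Chip geometry
#'
#' Describes the microfluidic chip: channel cross-sections, the segment lists
#' used to build the branch resistance network, tubing dimensions, the camera
#' pixel scale, and the three regions of interest (ROIs) used for
#' quantification. The default dimensions are those of the low-aspect chip
#' the pipeline targets: wide channels 1 mm across, narrow channels 0.1 mm,
#' uniform depth 0.05 mm.
#'
#' ROIs are pixel rectangles `c(row0, row1, col0, col1)`, 0-based and
#' half-open (`row0 <= r < row1`). Image rows run across the channel (the
#' direction in which the coflow interface moves); columns run along the
#' flow.
#'
#' @param width Wide-channel/chamber width w (mm).
#' @param depth Uniform channel depth h (mm); must not exceed `width`.
#' @param narrow_width Narrow-channel width (mm).
#' @param segments_ac,segments_vc Data frames (`length`, `width`, `depth`,
#'   all mm) describing the resistance path of the aggregation-channel and
#'   viscosity-channel branches downstream of their junction. `NULL` means
#'   the branch split is taken from a calibrated fraction instead (see
#'   [flow_split()]).
#' @param tubing_id Inner diameter of the delivery tubing (mm).
#' @param tubing_length Length of the delivery tubing (mm).
#' @param pixel_scale Image scale (micrometres per pixel).
#' @param frame_dim Rendered/expected frame size `c(rows, cols)` in pixels.
#' @param roi_mc,roi_ac,roi_vc ROI rectangles for the main chamber,
#'   aggregation chamber, and viscosity-sensing channel. The vc ROI must
#'   span the full channel width (`width` / `pixel_scale` * 1000 rows).
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(width = 1, depth = 0.05, narrow_width = 0.1,
                          segments_ac = NULL, segments_vc = NULL,
                          tubing_id = 0.25, tubing_length = 300,
                          pixel_scale = 5,
                          frame_dim = NULL,
                          roi_mc = NULL, roi_ac = NULL, roi_vc = NULL) {
  stopifnot(width > 0, depth > 0, narrow_width > 0,
            tubing_id > 0, tubing_length > 0, pixel_scale > 0)
  if (depth > width)
    stop("chip_geometry: depth must not exceed width (low-aspect channel)")

  w_px <- round(width * 1000 / pixel_scale)
  if (is.null(frame_dim) || is.null(roi_mc) || is.null(roi_ac) || is.null(roi_vc)) {
    lay <- chip_layout(w_px, roi_cols = round(1.8 / width * 1000 / pixel_scale))
    if (is.null(frame_dim)) frame_dim <- lay$frame_dim
    if (is.null(roi_mc)) roi_mc <- lay$roi_mc
    if (is.null(roi_ac)) roi_ac <- lay$roi_ac
    if (is.null(roi_vc)) roi_vc <- lay$roi_vc
  }
  g <- structure(list(
    width = width, depth = depth, narrow_width = narrow_width,
    segments_ac = segments_ac, segments_vc = segments_vc,
    tubing_id = tubing_id, tubing_length = tubing_length,
    pixel_scale = pixel_scale, width_px = w_px,
    frame_dim = as.integer(frame_dim),
    roi_mc = as.integer(roi_mc), roi_ac = as.integer(roi_ac),
    roi_vc = as.integer(roi_vc)
  ), class = "chip_geometry")
  for (nm in c("roi_mc", "roi_ac", "roi_vc")) {
    r <- g[[nm]]
    if (length(r) != 4L || any(r < 0) || r[1] >= r[2] || r[3] >= r[4])
      stop("chip_geometry: malformed ROI ", nm)
    if (r[2] > g$frame_dim[1] || r[4] > g$frame_dim[2])
      stop("chip_geometry: ROI ", nm, " exceeds the frame bounds")
  }
  if ((g$roi_vc[2] - g$roi_vc[1]) != w_px)
    stop("chip_geometry: vc ROI must span the full channel width (",
         w_px, " rows at ", pixel_scale, " um/px)")
  g
}

# Default stacked band layout: three horizontal channel bands (mc, ac, vc),
# each the full channel width tall, separated by wall margins.
chip_layout <- function(w_px, roi_cols, margin = 10L, col_margin = 20L) {
  r0 <- margin
  roi_mc <- c(r0, r0 + w_px, col_margin, col_margin + roi_cols)
  r0 <- r0 + w_px + 2L * margin
  roi_ac <- c(r0, r0 + w_px, col_margin, col_margin + roi_cols)
  r0 <- r0 + w_px + 2L * margin
  roi_vc <- c(r0, r0 + w_px, col_margin, col_margin + roi_cols)
  list(frame_dim = c(r0 + w_px + margin, roi_cols + 2L * col_margin),
       roi_mc = roi_mc, roi_ac = roi_ac, roi_vc = roi_vc)
}

#' Hydraulic resistance of a low-aspect rectangular channel
#'
#' Single-term aspect-corrected formula
#' `R = 12 mu L / (w h^3 (1 - 0.63 h / w))`, accurate to well under 1% for
#' the aspect ratios used here (h/w <= 0.5).
#'
#' @param length Channel length (mm).
#' @param width Channel width (mm).
#' @param depth Channel depth (mm); must not exceed `width`.
#' @param viscosity Fluid viscosity (cP).
#' @return Resistance in cP / mm^3 (pressure per unit mm^3/s flow).
#' @export
rectangular_channel_resistance <- function(length, width, depth, viscosity) {
  if (any(length <= 0) || any(width <= 0) || any(depth <= 0) || any(viscosity <= 0))
    stop("rectangular_channel_resistance: all arguments must be positive")
  if (any(depth > width))
    stop("rectangular_channel_resistance: depth must not exceed width")
  12 * viscosity * length / (width * depth^3 * (1 - 0.63 * depth / width))
}

#' Correction-factor model for the coflowing-stream viscometer
#'
#' The virtual-wall circuit model treats the coflow interface as a rigid
#' partition; its error is compensated by an empirical quartic in the
#' normalized interface position, calibrated for a 1 mm x 0.05 mm channel:
#' `Cf(a) = -12.038 a^4 + 26.171 a^3 - 20.770 a^2 + 7.156 a + 0.014`.
#' Because the polynomial is a fit, evaluation is restricted to a valid
#' interface domain; extrapolation is an error, not a clamp.
#'
#' @param coefficients Quartic coefficients, highest power first
#'   `c(c4, c3, c2, c1, c0)`.
#' @param domain Valid interface range `c(min, max)`.
#' @return An object of class `cf_model`.
#' @export
cf_model <- function(coefficients = c(-12.038, 26.171, -20.770, 7.156, 0.014),
                     domain = c(0.05, 0.95)) {
  stopifnot(length(coefficients) == 5, length(domain) == 2,
            domain[1] < domain[2], domain[1] >= 0, domain[2] <= 1)
  structure(list(coefficients = as.numeric(coefficients),
                 domain = as.numeric(domain)),
            class = "cf_model")
}

#' Evaluate the interface correction factor Cf
#'
#' @param alpha_b Normalized interface position(s) (blood-filled width
#'   fraction), inside `model$domain` unless `relax_domain = TRUE`.
#' @param model A [cf_model()].
#' @param relax_domain Allow evaluation outside the calibrated domain
#'   (used by tests of the raw polynomial; never by the pipeline).
#' @return Cf evaluated at `alpha_b`.
#' @export
correction_factor <- function(alpha_b, model = cf_model(), relax_domain = FALSE) {
  if (!relax_domain &&
      (any(alpha_b < model$domain[1]) || any(alpha_b > model$domain[2])))
    stop(sprintf("correction_factor: alpha_b outside the calibrated domain [%g, %g]",
                 model$domain[1], model$domain[2]))
  cf <- model$coefficients
  ((( cf[1] * alpha_b + cf[2]) * alpha_b + cf[3]) * alpha_b + cf[4]) * alpha_b + cf[5]
}

#' Blood viscosity from the coflow interface position
#'
#' Equal-pressure-drop (virtual wall) model of the coflowing streams in the
#' viscosity-sensing channel:
#' `mu_b = mu_r * (a / (1 - a)) * (Q_r / (Q_b - Q_ac)) * Cf(a)`,
#' where `a` is the normalized interface position, `Q_r` the reference-fluid
#' flow rate and `Q_b - Q_ac` the test-blood flow rate actually entering the
#' channel.
#'
#' @param alpha_b Normalized interface position, strictly inside (0, 1) and
#'   within the correction-factor domain.
#' @param q_r Reference-fluid flow rate (mL/h).
#' @param q_b Test-blood flow rate delivered by the syringe (mL/h).
#' @param q_ac Flow rate lost to the aggregation channel (mL/h).
#' @param mu_r Reference-fluid viscosity (cP).
#' @param model A [cf_model()].
#' @return Blood viscosity in cP.
#' @export
blood_viscosity <- function(alpha_b, q_r, q_b, q_ac = 0, mu_r = 1,
                            model = cf_model()) {
  if (any(q_r <= 0) || any(mu_r <= 0))
    stop("blood_viscosity: q_r and mu_r must be positive")
  if (any(q_b - q_ac <= 0))
    stop("blood_viscosity: degenerate flow, q_b must exceed q_ac")
  if (any(alpha_b <= 0) || any(alpha_b >= 1))
    stop("blood_viscosity: alpha_b must lie strictly inside (0, 1)")
  cf <- correction_factor(alpha_b, model)
  mu_r * (alpha_b / (1 - alpha_b)) * (q_r / (q_b - q_ac)) * cf
}

#' Interface position implied by a known viscosity (forward model)
#'
#' Inverts [blood_viscosity()] for the interface position: finds the unique
#' `alpha_b` in the correction-factor domain with
#' `blood_viscosity(alpha_b, ...) = mu_b`, by bisection on the strictly
#' increasing map `g(a) = a / (1 - a) * Cf(a)`. Used by the synthetic
#' renderer to place the interface, and well-posed because `g` is monotone
#' on the calibrated domain.
#'
#' @param mu_b Target test-fluid viscosity (cP).
#' @param mu_r Reference-fluid viscosity (cP).
#' @param q_r Reference-fluid flow rate (mL/h).
#' @param q_blood Test-fluid flow rate in the viscosity channel,
#'   i.e. `q_b - q_ac` (mL/h).
#' @param model A [cf_model()].
#' @param tol Bisection tolerance on the residual of `g`.
#' @return The interface position `alpha_b`.
#' @export
interface_from_viscosity <- function(mu_b, mu_r, q_r, q_blood,
                                     model = cf_model(), tol = 1e-10) {
  stopifnot(mu_b > 0, mu_r > 0, q_r > 0, q_blood > 0)
  target <- (mu_b / mu_r) * (q_blood / q_r)
  g <- function(a) (a / (1 - a)) * correction_factor(a, model) - target
  lo <- model$domain[1]; hi <- model$domain[2]
  flo <- g(lo); fhi <- g(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf(paste0(
      "interface_from_viscosity: viscosity ratio unreachable at these flow ",
      "rates (interface would sit outside [%g, %g]); adjust q_r to move the ",
      "interface back toward the channel center"),
      model$domain[1], model$domain[2]))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Wall shear rate in a low-aspect rectangular channel
#'
#' `gamma_dot = 6 Q / (w h^2)` with Q converted from mL/h to mm^3/s.
#'
#' @param q_mlh Flow rate (mL/h), may be a vector; non-negative.
#' @param width Channel width (mm).
#' @param depth Channel depth (mm).
#' @return Shear rate(s) in 1/s.
#' @export
shear_rate_rect <- function(q_mlh, width, depth) {
  if (width <= 0 || depth <= 0)
    stop("shear_rate_rect: width and depth must be positive")
  if (any(q_mlh < 0, na.rm = TRUE))
    stop("shear_rate_rect: flow rate must be non-negative")
  6 * mlh_to_mm3s(q_mlh) / (width * depth^2)
}

#' Shear rate of the blood stream in the viscosity-sensing channel
#'
#' The blood stream occupies only the fraction `alpha_b` of the channel
#' width, so `gamma_dot = 6 (Q_b - Q_ac) / (alpha_b w h^2)`; equivalently
#' [shear_rate_rect()] evaluated on the blood-filled width.
#'
#' @param q_b,q_ac Delivered and aggregation-channel flow rates (mL/h),
#'   with `q_b > q_ac >= 0`.
#' @param alpha_b Normalized interface position in (0, 1].
#' @param width,depth Channel width and depth (mm).
#' @return Shear rate in 1/s.
#' @export
shear_rate_viscosity_channel <- function(q_b, q_ac, alpha_b, width, depth) {
  if (any(alpha_b <= 0, na.rm = TRUE) || any(alpha_b > 1, na.rm = TRUE))
    stop("shear_rate_viscosity_channel: alpha_b must lie in (0, 1]")
  if (any(q_ac < 0, na.rm = TRUE) || any(q_b <= q_ac, na.rm = TRUE))
    stop("shear_rate_viscosity_channel: need q_b > q_ac >= 0")
  shear_rate_rect(q_b - q_ac, width, depth) / alpha_b
}

#' Split the delivered blood between the aggregation and viscosity branches
#'
#' Branch current divider at the junction: the aggregation channel takes
#' `Q_ac = Q_b * R_vc / (R_vc + R_ac)`. When no segment lists or branch
#' resistances are available the calibrated fraction `split` is used
#' directly (default 0.05, the measured blood split; glycerin-like fluids
#' run nearer 0.073).
#'
#' @param q_b Delivered flow rate (mL/h).
#' @param geometry Optional [chip_geometry()] carrying `segments_ac` /
#'   `segments_vc` branch descriptions.
#' @param viscosity Viscosity used to evaluate segment resistances (cP);
#'   cancels in the divider when both branches carry the same fluid.
#' @param split Calibrated fallback fraction `Q_ac / Q_b`.
#' @return List with `q_ac` and `q_vc` (mL/h), summing exactly to `q_b`.
#' @export
flow_split <- function(q_b, geometry = NULL, viscosity = 1, split = 0.05) {
  stopifnot(q_b >= 0)
  if (!is.null(geometry) && !is.null(geometry$segments_ac) &&
      !is.null(geometry$segments_vc)) {
    seg_r <- function(s) sum(rectangular_channel_resistance(
      s$length, s$width, s$depth, viscosity))
    r_ac <- seg_r(geometry$segments_ac)
    r_vc <- seg_r(geometry$segments_vc)
    if (r_ac + r_vc <= 0) stop("flow_split: degenerate zero total resistance")
    split <- r_vc / (r_ac + r_vc)
  }
  stopifnot(split >= 0, split <= 1)
  q_ac <- q_b * split
  list(q_ac = q_ac, q_vc = q_b - q_ac)
}

#' Flow state of the chip
#'
#' Records all flow rates for one operating point and enforces conservation
#' `Q_vc = Q_b - Q_ac`.
#'
#' @param q_b,q_r Syringe flow rates of blood and reference fluid (mL/h).
#' @param q_ac Aggregation-channel flow rate (mL/h).
#' @param q_mc Main-channel flow rate (mL/h), defaulting to `q_b`.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(q_b, q_r, q_ac = 0, q_mc = q_b) {
  stopifnot(q_b >= 0, q_r >= 0, q_ac >= 0, q_mc >= 0, q_ac <= q_b)
  structure(list(q_b = q_b, q_r = q_r, q_mc = q_mc,
                 q_ac = q_ac, q_vc = q_b - q_ac),
            class = "flow_state")
}

#' Transit time through the delivery tubing
#'
#' Plug-flow estimate `t = pi (id/2)^2 L / Q` of the time a fluid element
#' needs from the needle tip to the chip inlet.
#'
#' @param tubing_id Tubing inner diameter (mm).
#' @param tubing_length Tubing length (mm); zero length gives zero time.
#' @param q_mlh Flow rate (mL/h), strictly positive.
#' @return Transit time in seconds.
#' @export
transit_time <- function(tubing_id, tubing_length, q_mlh) {
  stopifnot(tubing_id > 0, tubing_length >= 0)
  if (q_mlh <= 0)
    stop("transit_time: infinite transit, flow rate must be positive")
  pi * (tubing_id / 2)^2 * tubing_length / mlh_to_mm3s(q_mlh)
}
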