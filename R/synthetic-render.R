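# Synthetic chip renderer: draws ground-truthed frame bursts of the three
# channel bands (main chamber, aggregation chamber, viscosity-sensing
# channel) and packages whole timelapse runs as multi-page TIFF + JSON
# ground-truth manifest.

#' Render settings for the synthetic chip
#'
#' @param background Background / reference-fluid intensity (8-bit).
#' @param beta Linear hematocrit attenuation (intensity units per unit
#'   hematocrit fraction): chamber blood is drawn at
#'   `background - beta * Hct`.
#' @param particle_density Tracer particle density (per mm^2).
#' @param particle_sigma Gaussian tracer radius parameter (px).
#' @param particle_amp Tracer peak darkening (intensity units).
#' @param noise_sd Additive Gaussian noise sigma (intensity units).
#' @param vc_contrast Intensity deficit of the test stream in the
#'   viscosity-sensing channel, or `NULL` to reuse `beta * Hct`. Dilute
#'   tracer suspensions (Newtonian calibration fluids) need an explicit
#'   value because their hematocrit barely darkens the stream.
#' @param warn_disp_px Particle displacement (px per burst interval) above
#'   which a PIV aliasing warning is emitted.
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(background = 220, beta = 200,
                            particle_density = 2400, particle_sigma = 1,
                            particle_amp = 50, noise_sd = 0,
                            vc_contrast = NULL, warn_disp_px = 6) {
  stopifnot(background > 0, background <= 255, beta >= 0,
            particle_density >= 0, particle_sigma > 0, particle_amp >= 0,
            noise_sd >= 0)
  if (!is.null(vc_contrast)) stopifnot(vc_contrast > 0)
  structure(list(background = background, beta = beta,
                 particle_density = particle_density,
                 particle_sigma = particle_sigma,
                 particle_amp = particle_amp, noise_sd = noise_sd,
                 vc_contrast = vc_contrast, warn_disp_px = warn_disp_px),
            class = "render_settings")
}

# Draw Gaussian dark tracers at continuous (row, col) positions into a frame.
draw_particles <- function(frame, pos, amp, sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  r3 <- ceiling(3 * sigma) + 1
  for (i in seq_len(nrow(pos))) {
    pr <- pos[i, 1]; pc <- pos[i, 2]
    if (pr < 1 - r3 || pr > nr + r3 || pc < 1 - r3 || pc > nc + r3) next
    rr <- max(1, floor(pr) - r3):min(nr, ceiling(pr) + r3)
    cc <- max(1, floor(pc) - r3):min(nc, ceiling(pc) + r3)
    g <- outer(exp(-(rr - pr)^2 / (2 * sigma^2)),
               exp(-(cc - pc)^2 / (2 * sigma^2)))
    frame[rr, cc] <- frame[rr, cc] - amp * g
  }
  frame
}

# Sample tracer positions for one chamber band. Rows span the band; columns
# extend past the frame so that advected tracers enter/leave realistically.
sample_particles <- function(band_rows, n_cols, pixel_scale, density, margin = 8) {
  nr <- band_rows[2] - band_rows[1]
  area_mm2 <- (nr * pixel_scale / 1000) * ((n_cols + 2 * margin) * pixel_scale / 1000)
  n <- stats::rpois(1, density * area_mm2)
  cbind(stats::runif(n, band_rows[1] + 1, band_rows[2]),
        stats::runif(n, 1 - margin, n_cols + margin))
}

#' Render one frame burst of the synthetic chip
#'
#' Draws the chip at one trigger instant: main and aggregation chambers at
#' their hematocrit-attenuated intensity with advected tracer particles
#' (the aggregation chamber additionally scaled down by the aggregation
#' deficit), and the viscosity-sensing channel split at the interface row
#' `round(alpha_b * width_px)` between test-stream and reference-fluid
#' intensity. Frames within the burst differ only by the frozen-flow
#' advection of the tracers; the aggregation chamber reuses the main
#' chamber's tracer layout (chambers have identical dimensions) so that
#' paired intensity readings are free of seeding noise.
#'
#' Consumes the R random number stream (tracer positions, noise); callers
#' wanting reproducibility must seed beforehand, as [generate_dataset()]
#' does.
#'
#' @param state List with elements `hct`, `alpha_b`, `u_mc`, `u_ac` (mm/s),
#'   `deficit` (fractional), `on` (logical delivery state).
#' @param geometry A [chip_geometry()].
#' @param settings A [render_settings()].
#' @param burst_length Number of frames.
#' @param burst_dt Intra-burst frame interval (s).
#' @return List of `burst_length` integer-valued matrices in \[0, 255\].
#' @export
render_burst <- function(state, geometry, settings, burst_length = 2,
                         burst_dt = 0.001) {
  dim <- geometry$frame_dim
  ps <- geometry$pixel_scale
  i0 <- settings$background
  blood_i <- max(i0 - settings$beta * state$hct, 0)
  vc_blood_i <- if (is.null(settings$vc_contrast)) blood_i else
    max(i0 - settings$vc_contrast, 0)

  disp_mc <- state$u_mc * burst_dt * 1000 / ps  # px per burst interval
  disp_ac <- state$u_ac * burst_dt * 1000 / ps
  if (max(disp_mc, disp_ac) > settings$warn_disp_px)
    warning("render_burst: particle displacement exceeds half an ",
            "interrogation window; PIV will alias")

  mc <- geometry$roi_mc; ac <- geometry$roi_ac; vc <- geometry$roi_vc
  # particle layout shared by both chambers (identical dimensions), row
  # coordinates relative to the band; tails are confined to the channel
  pos <- sample_particles(c(0, mc[2] - mc[1]), dim[2], ps,
                          settings$particle_density)

  # interface row index: blood occupies the top `k` rows of the vc band
  k <- round(state$alpha_b * geometry$width_px)
  vc_rows_blood <- if (k > 0) (vc[1] + 1):(vc[1] + k) else integer(0)
  vc_rows_ref <- if (k < geometry$width_px) (vc[1] + k + 1):vc[2] else integer(0)

  band_nr <- mc[2] - mc[1]
  frames <- vector("list", burst_length)
  for (f in seq_len(burst_length)) {
    fr <- matrix(i0, dim[1], dim[2])
    if (length(vc_rows_blood)) fr[vc_rows_blood, ] <- vc_blood_i
    if (length(vc_rows_ref)) fr[vc_rows_ref, ] <- i0

    adv <- (f - 1)
    band <- function(disp) {
      p <- pos; p[, 2] <- p[, 2] + adv * disp
      draw_particles(matrix(blood_i, band_nr, dim[2]), p,
                     settings$particle_amp, settings$particle_sigma)
    }
    fr[(mc[1] + 1):mc[2], ] <- band(disp_mc)
    # aggregation deficit darkens the whole chamber content multiplicatively
    fr[(ac[1] + 1):ac[2], ] <- band(disp_ac) * (1 - state$deficit)

    if (settings$noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, settings$noise_sd),
                        nrow(fr), ncol(fr))
    frames[[f]] <- pmax(pmin(round(fr), 255), 0)
  }
  frames
}

#' Generate a ground-truthed synthetic timelapse dataset
#'
#' For each trigger: evaluates the delivery schedule, delivered hematocrit,
#' phantom viscosity, the flow split, the interface position implied by the
#' coflow model, and the chamber velocities; renders the burst; and records
#' the ground truth. Output is a trigger-major multi-page 8-bit TIFF plus a
#' JSON manifest echoing the full configuration. Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario A [flow_scenario()].
#' @param blood A [blood_model()].
#' @param geometry A [chip_geometry()].
#' @param settings A [render_settings()].
#' @param out_tiff Output TIFF path.
#' @param out_manifest Output JSON manifest path (default: TIFF path with
#'   `.json` extension).
#' @return Invisibly, a list with `tiff`, `manifest`, and the ground-truth
#'   data frame `truth` (one row per trigger).
#' @export
generate_dataset <- function(scenario, blood, geometry, settings,
                             out_tiff, out_manifest = NULL) {
  stopifnot(inherits(scenario, "flow_scenario"), inherits(blood, "blood_model"),
            inherits(geometry, "chip_geometry"),
            inherits(settings, "render_settings"))
  if (is.null(out_manifest))
    out_manifest <- sub("\\.tiff?$", ".json", out_tiff)
  set.seed(scenario$seed)

  n_trig <- floor(scenario$duration / scenario$trigger_period)
  times <- (seq_len(n_trig) - 1) * scenario$trigger_period
  states <- schedule_state(times, scenario)
  hcts <- delivered_hematocrit(times, scenario, blood)

  w <- geometry$width; h <- geometry$depth
  pages <- vector("list", n_trig * scenario$burst_length)
  truth <- vector("list", n_trig)
  for (i in seq_len(n_trig)) {
    on <- states[i] == "on"
    hct <- hcts[i]
    mu_b <- phantom_viscosity(hct, blood$c_dex, blood)
    qs <- flow_split(scenario$q_b, geometry, split = scenario$split)
    q_ac <- if (on) qs$q_ac else 0
    q_b_on <- scenario$q_b
    alpha_b <- tryCatch(
      interface_from_viscosity(mu_b, scenario$mu_r, scenario$q_r,
                               q_b_on - qs$q_ac),
      error = function(e) stop(
        "generate_dataset: trigger ", i, " (t = ", times[i], " s): ",
        conditionMessage(e), call. = FALSE))
    u_mc <- if (on) mlh_to_mm3s(q_b_on) / (w * h) else 0
    u_ac <- if (on) mlh_to_mm3s(q_ac) / (w * h) else 0
    shear_ac <- shear_rate_rect(q_ac, w, h)
    deficit <- phantom_aggregation_deficit(hct, blood$c_dex,
                                           blood$aggregability, shear_ac)
    st <- list(hct = hct, alpha_b = alpha_b, u_mc = u_mc, u_ac = u_ac,
               deficit = deficit, on = on)
    burst <- render_burst(st, geometry, settings,
                          scenario$burst_length, scenario$burst_dt)
    for (f in seq_along(burst))
      pages[[(i - 1) * scenario$burst_length + f]] <- burst[[f]] / 255
    truth[[i]] <- data.frame(
      t = times[i], state = states[i], hct = hct, mu_b = mu_b,
      alpha_b = alpha_b, u_mc = u_mc, u_ac = u_ac,
      q_ac = q_ac, q_vc = if (on) q_b_on - q_ac else 0,
      ai = deficit, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  tiff::writeTIFF(pages, out_tiff, bits.per.sample = 8, compression = "LZW")
  manifest <- list(
    seed = scenario$seed,
    scenario = unclass(scenario),
    blood = unclass(blood),
    geometry = unclass(geometry),
    render = unclass(settings),
    triggers = truth)
  jsonlite::write_json(manifest, out_manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(tiff = out_tiff, manifest = out_manifest, truth = truth))
}

#' Read a ground-truth manifest
#'
#' @param path Manifest JSON path written by [generate_dataset()].
#' @return List with the echoed configuration and the `triggers` data frame.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$triggers <- as.data.frame(m$triggers)
  m
}
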