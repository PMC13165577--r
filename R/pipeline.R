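# Orchestration: a single config drives simulate -> analyze -> roundtrip,
# so closed-loop checks cannot drift apart. Configs are plain nested lists
# (YAML on disk); every section is validated against its constructor and
# unknown keys are rejected.

#' Analysis parameters
#'
#' @param window_px Interrogation window (px); `NULL` derives it from the
#'   geometry's pixel scale via [piv_window_px()].
#' @param overlap Window overlap fraction.
#' @param median_threshold,std_threshold Vector-validation thresholds
#'   (see [validate_vectors()]).
#' @param plateau_window_frac,plateau_cv_threshold Plateau-selection
#'   parameters (see [plateau_velocity()]).
#' @param plateau_override Fixed plateau velocity (mm/s) bypassing automatic
#'   selection, or `NULL`.
#' @param ai_mode `"raw"` (default) or `"subtracted"`: whether AI uses raw
#'   chamber intensities or intensities relative to the first-trigger
#'   background, guarded against near-zero denominators.
#' @param smooth_window AI smoothing window for `AI_max`.
#' @return A validated list of analysis parameters.
#' @export
analysis_params <- function(window_px = NULL, overlap = 0.5,
                            median_threshold = 2, std_threshold = 3,
                            plateau_window_frac = 0.1,
                            plateau_cv_threshold = 0.05,
                            plateau_override = NULL,
                            ai_mode = c("raw", "subtracted"),
                            smooth_window = 11) {
  ai_mode <- match.arg(ai_mode)
  if (!is.null(window_px)) stopifnot(window_px >= 3)
  structure(list(window_px = window_px, overlap = overlap,
                 median_threshold = median_threshold,
                 std_threshold = std_threshold,
                 plateau_window_frac = plateau_window_frac,
                 plateau_cv_threshold = plateau_cv_threshold,
                 plateau_override = plateau_override,
                 ai_mode = ai_mode, smooth_window = smooth_window),
            class = "analysis_params")
}

check_keys <- function(given, constructor, section) {
  allowed <- names(formals(constructor))
  unknown <- setdiff(names(given), allowed)
  if (length(unknown))
    stop("run_config: unknown key(s) in ", section, ": ",
         paste(unknown, collapse = ", "))
}

#' Build a validated run configuration
#'
#' Each section is a list of arguments for the corresponding constructor
#' ([chip_geometry()], [flow_scenario()], [blood_model()],
#' [render_settings()], [analysis_params()]); unknown keys are rejected.
#' `seed` overrides any seed in the scenario section.
#'
#' @param geometry,scenario,blood,render,analysis Named lists of section
#'   arguments (may be empty for defaults).
#' @param seed Integer seed (required here or in `scenario`).
#' @return An object of class `run_config` with constructed sections.
#' @export
run_config <- function(geometry = list(), scenario = list(), blood = list(),
                       render = list(), analysis = list(), seed = NULL) {
  check_keys(geometry, chip_geometry, "geometry")
  check_keys(scenario, flow_scenario, "scenario")
  check_keys(blood, blood_model, "blood")
  check_keys(render, render_settings, "render")
  check_keys(analysis, analysis_params, "analysis")
  if (!is.null(seed)) scenario$seed <- seed
  structure(list(
    geometry = do.call(chip_geometry, geometry),
    scenario = do.call(flow_scenario, scenario),
    blood = do.call(blood_model, blood),
    render = do.call(render_settings, render),
    analysis = do.call(analysis_params, analysis),
    sections = list(geometry = geometry, scenario = scenario, blood = blood,
                    render = render, analysis = analysis)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with sections `geometry`, `scenario`, `blood`,
#'   `render`, `analysis` and optional top-level `seed`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("geometry", "scenario", "blood", "render", "analysis", "seed", "mode")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("read_run_config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  run_config(geometry = y$geometry %||% list(),
             scenario = y$scenario %||% list(),
             blood = y$blood %||% list(),
             render = y$render %||% list(),
             analysis = y$analysis %||% list(),
             seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_config_echo <- function(config, path) {
  yaml::write_yaml(c(config$sections,
                     list(seed = config$scenario$seed)), path)
}

#' Preset configurations
#'
#' Ready-made study conditions:
#' \describe{
#'   \item{control}{Hct 50% RBCs in plain PBS-like medium: no aggregant, no
#'     syringe sedimentation; all readouts constant over time.}
#'   \item{dextran20}{Hct 50% in 20 mg/mL dextran: aggregating, sedimenting
#'     test blood; viscosity and interface rise over the run.}
#'   \item{newtonian}{Newtonian calibration fluid (glycerin-like, viscosity
#'     `mu_b` cP) carrying a dilute RBC tracer; aggregation-channel split
#'     7.3% as measured for such fluids.}
#'   \item{thermal}{Heat-exposed RBCs in 20 mg/mL dextran: aggregability and
#'     sedimentation both strongly reduced.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param duration Run duration (s).
#' @param mu_b Newtonian test-fluid viscosity (cP), `newtonian` preset only.
#' @param noise_sd Render noise sigma.
#' @param ... Extra `scenario` overrides (e.g. `q_b`, `q_r`).
#' @return A `run_config`.
#' @export
preset_config <- function(name = c("control", "dextran20", "newtonian", "thermal"),
                          seed, duration = 60, mu_b = 2.569, noise_sd = 0, ...) {
  name <- match.arg(name)
  scen <- switch(name,
    control   = list(q_b = 0.4, q_r = 2.5, duration = duration),
    dextran20 = list(q_b = 0.4, q_r = 1.8, duration = duration),
    newtonian = list(q_b = 1.0, q_r = 2.5, duration = duration, split = 0.073),
    thermal   = list(q_b = 0.4, q_r = 1.8, duration = duration))
  scen <- utils::modifyList(scen, list(...))
  blood <- switch(name,
    control   = list(hct0 = 0.5, c_dex = 0, sed_amplitude = 0),
    dextran20 = list(hct0 = 0.5, c_dex = 20, sed_amplitude = 0.15),
    newtonian = list(hct0 = 0.03, c_dex = 0, aggregability = 0,
                     sed_amplitude = 0, fixed_viscosity = mu_b),
    thermal   = list(hct0 = 0.5, c_dex = 20, aggregability = 0.25,
                     sed_amplitude = 0.03))
  rend <- list(noise_sd = noise_sd)
  if (name == "newtonian") rend$vc_contrast <- 60
  run_config(scenario = scen, blood = blood, render = rend, seed = seed)
}

#' Simulate a synthetic dataset from a configuration
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, list with `tiff`, `manifest`, `config_echo`, `truth`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- generate_dataset(config$scenario, config$blood, config$geometry,
                          config$render,
                          file.path(out_dir, "dataset.tiff"),
                          file.path(out_dir, "manifest.json"))
  echo <- file.path(out_dir, "config.yaml")
  write_config_echo(config, echo)
  invisible(list(tiff = res$tiff, manifest = res$manifest,
                 config_echo = echo, truth = res$truth))
}

# Read a burst stack back as 0..255 matrices, trigger-major.
read_burst_stack <- function(path, burst_length) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) %% burst_length != 0)
    stop("read_burst_stack: page count ", length(pages),
         " is not a multiple of the burst length ", burst_length,
         " (truncated stack?)")
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 255)
  })
}

#' Analyze a burst stack into channel time series and rheology
#'
#' Per trigger: micro-PIV over the mc and ac ROIs (first burst pair),
#' vector validation, ROI-mean speeds; raw ROI intensities; Otsu interface
#' in the vc ROI. Then: plateau calibration of flow rates, per-trigger AI,
#' viscosity and shear. Writes `timeseries.csv`, `rheology.csv`,
#' `summary.json`, and `analyze.log` into `out_dir`.
#'
#' @param config A `run_config` (geometry/scenario/analysis sections used).
#' @param tiff Input multi-page TIFF path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-trigger data frame `series`, the
#'   rheology data frame `rheology`, and the `summary` list.
#' @export
run_analyze <- function(config, tiff, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$geometry
  sc <- config$scenario
  an <- config$analysis
  t_start <- proc.time()[["elapsed"]]

  pages <- read_burst_stack(tiff, sc$burst_length)
  if (!all(dim(pages[[1]]) == g$frame_dim))
    stop("run_analyze: frame size ", paste(dim(pages[[1]]), collapse = "x"),
         " does not match the configured geometry ",
         paste(g$frame_dim, collapse = "x"))
  n_trig <- length(pages) / sc$burst_length
  times <- (seq_len(n_trig) - 1) * sc$trigger_period
  win <- an$window_px %||% piv_window_px(g$pixel_scale)
  t_read <- proc.time()[["elapsed"]]

  speed_in_roi <- function(f1, f2, roi) {
    fld <- cross_correlate_pair(f1, f2, win, an$overlap, roi)
    if (!any(fld$valid)) return(list(u = NA_real_, n = 0L))
    fld <- tryCatch(
      validate_vectors(fld, an$median_threshold, an$std_threshold),
      error = function(e) NULL)
    if (is.null(fld)) return(list(u = NA_real_, n = 0L))
    u <- suppressWarnings(roi_mean_velocity(fld, g$pixel_scale, sc$burst_dt))
    list(u = u, n = sum(fld$valid))
  }

  rows <- vector("list", n_trig)
  for (i in seq_len(n_trig)) {
    f1 <- pages[[(i - 1) * sc$burst_length + 1]]
    f2 <- pages[[(i - 1) * sc$burst_length + 2]]
    mc <- speed_in_roi(f1, f2, g$roi_mc)
    ac <- speed_in_roi(f1, f2, g$roi_ac)
    iface <- suppressWarnings(
      interface_alpha(f1, g$roi_vc, g$pixel_scale, g$width,
                      background_hint = config$render$background))
    rows[[i]] <- data.frame(
      t = times[i], u_mc = mc$u, u_ac = ac$u,
      i_mc = roi_mean_intensity(f1, g$roi_mc),
      i_ac = roi_mean_intensity(f1, g$roi_ac),
      w_b = iface$wb, alpha_b = iface$alpha_b,
      n_valid_mc = mc$n, n_valid_ac = ac$n)
  }
  series <- do.call(rbind, rows)
  t_piv <- proc.time()[["elapsed"]]

  plateau <- an$plateau_override %||% tryCatch(
    plateau_velocity(series$u_mc, an$plateau_window_frac,
                     an$plateau_cv_threshold),
    error = function(e) NA_real_)
  if (is.finite(plateau) && plateau > 0) {
    q <- calibrate_flow_rates(series$u_mc, series$u_ac, plateau, sc$q_b)
  } else {
    q <- list(q_mc = rep(NA_real_, n_trig), q_ac = rep(NA_real_, n_trig))
  }

  if (an$ai_mode == "subtracted") {
    i_mc_eff <- series$i_mc - series$i_mc[1]
    i_ac_eff <- series$i_ac - series$i_ac[1]
    i_mc_eff[abs(i_mc_eff) <= 10] <- NA_real_
    ai <- suppressWarnings(aggregation_index(i_mc_eff, i_ac_eff))
  } else {
    ai <- suppressWarnings(aggregation_index(series$i_mc, series$i_ac))
  }
  visc <- viscosity_series(series$alpha_b, q$q_mc, q$q_ac,
                           sc$q_r, sc$mu_r, g)
  rheology <- data.frame(
    t = series$t, q_mc_mlh = q$q_mc, q_ac_mlh = q$q_ac,
    q_vc_mlh = q$q_mc - q$q_ac,
    mu_b_cp = visc$mu_b, shear_s1 = visc$shear, ai = ai)
  t_rheo <- proc.time()[["elapsed"]]

  summary <- list(
    n_triggers = n_trig,
    n_missing_mu = sum(is.na(visc$mu_b)),
    plateau_u_mc = plateau,
    ai_max = if (all(is.na(ai))) NA else ai_max(ai, an$smooth_window),
    mean_mu_b = mean(visc$mu_b, na.rm = TRUE),
    median_mu_b = stats::median(visc$mu_b, na.rm = TRUE),
    mean_shear = mean(visc$shear, na.rm = TRUE),
    cov_wb_pct = tryCatch(coefficient_of_variation(series$w_b),
                          error = function(e) NA_real_),
    mean_alpha_b = mean(series$alpha_b, na.rm = TRUE),
    window_px = win)

  utils::write.csv(series, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(rheology, file.path(out_dir, "rheology.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("triggers: %d", n_trig),
    sprintf("interrogation window: %d px, overlap %.2f", win, an$overlap),
    sprintf("invalid-vector triggers (mc): %d", sum(series$n_valid_mc == 0)),
    sprintf("missing mu_b triggers: %d", sum(is.na(visc$mu_b))),
    sprintf("read: %.2f s, piv+imagequant: %.2f s, rheology: %.2f s",
            t_read - t_start, t_piv - t_read, t_rheo - t_piv)),
    file.path(out_dir, "analyze.log"))
  invisible(list(series = series, rheology = rheology, summary = summary))
}

#' Simulate, analyze, and report ground-truth recovery errors
#'
#' Joins the ground-truth manifest and the analysis results on trigger time
#' and reports per-trigger and aggregate recovery errors for viscosity,
#' interface position, velocity, and AI.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (`sim/` and `analysis/` are created
#'   inside; the report is written to `roundtrip.json`).
#' @return Invisibly, list with `per_trigger` data frame and `aggregate`
#'   list.
#' @export
run_roundtrip <- function(config, out_dir) {
  sim <- run_simulate(config, file.path(out_dir, "sim"))
  res <- run_analyze(config, sim$tiff, file.path(out_dir, "analysis"))
  truth <- sim$truth
  got <- merge(truth, cbind(res$series, res$rheology[-1]), by = "t")
  if (nrow(got) != nrow(truth))
    stop("run_roundtrip: trigger times of manifest and results do not align")
  on <- got$state == "on"
  per <- data.frame(
    t = got$t, state = got$state,
    mu_rel_err_pct = ifelse(is.na(got$mu_b_cp), NA,
                            100 * (got$mu_b_cp - got$mu_b) / got$mu_b),
    alpha_abs_err = got$alpha_b.y - got$alpha_b.x,
    u_mc_rel_err_pct = ifelse(got$u_mc.x > 0,
                              100 * (got$u_mc.y - got$u_mc.x) / got$u_mc.x, NA),
    ai_abs_err = got$ai.y - got$ai.x)
  aggregate <- list(
    n = nrow(per),
    mu_median_abs_rel_err_pct = stats::median(abs(per$mu_rel_err_pct[on]),
                                              na.rm = TRUE),
    mu_max_abs_rel_err_pct = suppressWarnings(
      max(abs(per$mu_rel_err_pct[on]), na.rm = TRUE)),
    alpha_max_abs_err = suppressWarnings(
      max(abs(per$alpha_abs_err[on]), na.rm = TRUE)),
    u_mc_median_abs_rel_err_pct = stats::median(abs(per$u_mc_rel_err_pct[on]),
                                                na.rm = TRUE),
    ai_max_abs_err = suppressWarnings(max(abs(per$ai_abs_err[on]),
                                          na.rm = TRUE)))
  jsonlite::write_json(list(per_trigger = per, aggregate = aggregate),
                       file.path(out_dir, "roundtrip.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_trigger = per, aggregate = aggregate))
}
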