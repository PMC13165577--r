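# Phantom blood models and delivery schedules for the synthetic chip.
#
# The generator emulates the experimentally dominant disturbance of
# continuous syringe delivery: RBC sedimentation inside the syringe barrel,
# which raises the hematocrit actually delivered to the chip over time.
# Sedimentation accrues faster while the syringe is stopped, which is what
# makes no-delivery waiting time and on-off schedules interesting.

#' Synthetic blood model
#'
#' Parameters of the phantom test fluid: base hematocrit, aggregant (dextran)
#' concentration, an aggregability scalar (1 = untreated RBCs, 0 = fully
#' heat-ablated), and the syringe-sedimentation law. `fixed_viscosity`
#' overrides the hematocrit-viscosity law to emulate a Newtonian calibration
#' fluid (glycerin with tracer RBCs).
#'
#' @param hct0 Initial delivered hematocrit (volume fraction, 0 < hct0 < 0.8).
#' @param c_dex Dextran concentration in the suspending medium (mg/mL).
#' @param aggregability Aggregability scalar in \[0, 1\].
#' @param sed_amplitude Dimensionless asymptotic fractional rise of delivered
#'   hematocrit due to sedimentation (0 disables sedimentation).
#' @param sed_tau Sedimentation time constant (s).
#' @param stasis_kappa Acceleration factor (>= 1) applied to the
#'   sedimentation clock while delivery is stopped.
#' @param fixed_viscosity Fixed Newtonian viscosity (cP) overriding the
#'   hematocrit law, or `NULL`.
#' @param medium_slope Slope of medium viscosity in dextran concentration
#'   (cP per mg/mL); medium viscosity is `1 + medium_slope * c_dex`.
#' @return An object of class `blood_model`.
#' @export
blood_model <- function(hct0 = 0.5, c_dex = 0, aggregability = 1,
                        sed_amplitude = 0, sed_tau = 600, stasis_kappa = 6,
                        fixed_viscosity = NULL, medium_slope = 0.03) {
  stopifnot(hct0 > 0, hct0 < 0.8, c_dex >= 0,
            aggregability >= 0, aggregability <= 1,
            sed_amplitude >= 0, sed_tau > 0, stasis_kappa >= 1)
  if (!is.null(fixed_viscosity)) stopifnot(fixed_viscosity > 0)
  structure(list(hct0 = hct0, c_dex = c_dex, aggregability = aggregability,
                 sed_amplitude = sed_amplitude, sed_tau = sed_tau,
                 stasis_kappa = stasis_kappa,
                 fixed_viscosity = fixed_viscosity,
                 medium_slope = medium_slope),
            class = "blood_model")
}

#' Delivery scenario
#'
#' Flow rates, imaging cadence, and the on-off delivery schedule. The
#' schedule starts with an optional no-delivery waiting time `t_wait`
#' (syringe loaded but stopped), followed either by continuous delivery or
#' by periodic on/off blocks of `t_on` / `t_off` seconds.
#'
#' @param q_b Blood (test-fluid) flow rate while delivering (mL/h).
#' @param q_r Reference-fluid flow rate (mL/h).
#' @param mu_r Reference-fluid viscosity (cP).
#' @param duration Total imaged duration (s).
#' @param trigger_period Time between frame bursts (s).
#' @param burst_length Frames per burst (>= 2 for PIV).
#' @param burst_dt Intra-burst frame interval (s).
#' @param t_wait Initial no-delivery waiting time (s).
#' @param t_on,t_off Periodic delivery on/off block lengths (s); both `NULL`
#'   for continuous delivery.
#' @param split Fraction of delivered blood entering the aggregation channel.
#' @param seed Integer RNG seed; mandatory, the generator is deterministic.
#' @return An object of class `flow_scenario`.
#' @export
flow_scenario <- function(q_b = 0.4, q_r = 0.8, mu_r = 1.0, duration = 60,
                          trigger_period = 1, burst_length = 2,
                          burst_dt = 0.001, t_wait = 0,
                          t_on = NULL, t_off = NULL, split = 0.05,
                          seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("flow_scenario: an integer seed is required for reproducibility")
  stopifnot(q_b > 0, q_r > 0, mu_r > 0, duration > 0, trigger_period > 0,
            burst_length >= 2, burst_dt > 0, t_wait >= 0,
            split >= 0, split < 1)
  if (xor(is.null(t_on), is.null(t_off)))
    stop("flow_scenario: t_on and t_off must be given together")
  if (!is.null(t_on)) stopifnot(t_on > 0, t_off > 0)
  structure(list(q_b = q_b, q_r = q_r, mu_r = mu_r, duration = duration,
                 trigger_period = trigger_period,
                 burst_length = as.integer(burst_length),
                 burst_dt = burst_dt, t_wait = t_wait,
                 t_on = t_on, t_off = t_off, split = split,
                 seed = as.integer(seed)),
            class = "flow_scenario")
}

#' Delivery state at a given time
#'
#' @param t Time(s) since the start of the schedule (s).
#' @param scenario A [flow_scenario()].
#' @return Character vector, `"on"` or `"off"` per time point.
#' @export
schedule_state <- function(t, scenario) {
  stopifnot(all(t >= 0))
  state <- rep("on", length(t))
  state[t < scenario$t_wait] <- "off"
  if (!is.null(scenario$t_on)) {
    tt <- pmax(t - scenario$t_wait, 0)
    phase <- tt %% (scenario$t_on + scenario$t_off)
    state[t >= scenario$t_wait & phase >= scenario$t_on] <- "off"
  }
  state
}

# Sedimentation clock: elapsed effective time, accruing at rate 1 while
# delivering and rate kappa while stopped. Piecewise linear in t.
sedimentation_clock <- function(t, scenario, kappa) {
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    grid <- seq(0, ti, by = min(scenario$trigger_period, 1) / 4)
    if (grid[length(grid)] < ti) grid <- c(grid, ti)
    st <- schedule_state(grid[-length(grid)], scenario)
    rates <- ifelse(st == "on", 1, kappa)
    sum(diff(grid) * rates)
  }, numeric(1))
}

#' Hematocrit delivered to the chip at time t
#'
#' Saturating-exponential sedimentation law
#' `Hct(t) = Hct0 * (1 + a * A * (1 - exp(-s(t) / tau)))`, where the
#' sedimentation clock `s(t)` runs at rate 1 during delivery and rate
#' `stasis_kappa` while the syringe is stopped. Thermally damaged RBCs
#' (low aggregability `a`) sediment less, which couples the two parameters.
#' Capped at 0.8.
#'
#' @param t Time(s) since schedule start (s).
#' @param scenario A [flow_scenario()].
#' @param model A [blood_model()].
#' @return Delivered hematocrit fraction(s).
#' @export
delivered_hematocrit <- function(t, scenario, model) {
  s <- sedimentation_clock(t, scenario, model$stasis_kappa)
  hct <- model$hct0 * (1 + model$aggregability * model$sed_amplitude *
                         (1 - exp(-s / model$sed_tau)))
  pmin(hct, 0.8)
}

#' Phantom viscosity of the synthetic test fluid
#'
#' Krieger-Dougherty-type hematocrit law on top of a medium viscosity linear
#' in dextran concentration:
#' `mu_b = (1 + medium_slope * c_dex) * (1 - Hct / 0.98)^(-2.5)`.
#' A `fixed_viscosity` in the model (Newtonian calibration fluid) takes
#' precedence.
#'
#' @param hct Hematocrit fraction(s), below 0.98.
#' @param c_dex Dextran concentration (mg/mL).
#' @param model A [blood_model()] supplying `medium_slope` and the optional
#'   `fixed_viscosity` override.
#' @return Viscosity in cP.
#' @export
phantom_viscosity <- function(hct, c_dex = 0, model = blood_model()) {
  if (!is.null(model$fixed_viscosity))
    return(rep(model$fixed_viscosity, length(hct)))
  if (any(hct < 0) || any(hct >= 0.98))
    stop("phantom_viscosity: hematocrit must lie in [0, 0.98)")
  mu_medium <- 1 + model$medium_slope * c_dex
  mu_medium * (1 - hct / 0.98)^(-2.5)
}

#' Fractional aggregation-induced intensity deficit
#'
#' Models how much darker the aggregation chamber appears than the main
#' chamber: `deficit = gain * a * f_dex(c_dex) * (1 - Hct) * g(shear)`,
#' clamped to \[0, 0.5\]. The dextran response `f_dex(c) = (c/c_peak)
#' exp(1 - c/c_peak)` is unimodal with its peak at `c_peak` (rouleaux
#' formation is maximal at intermediate aggregant concentration), and
#' `g(shear) = 1 / (1 + shear/shear_half)` decays with shear since high
#' shear disperses aggregates.
#'
#' @param hct Hematocrit fraction in \[0, 1).
#' @param c_dex Dextran concentration (mg/mL).
#' @param aggregability Aggregability scalar in \[0, 1\].
#' @param shear Shear rate in the aggregation chamber (1/s).
#' @param gain Overall deficit gain.
#' @param c_peak Dextran concentration of maximal aggregation (mg/mL).
#' @param shear_half Shear rate halving the deficit (1/s).
#' @return Fractional intensity deficit in \[0, 0.5\].
#' @export
phantom_aggregation_deficit <- function(hct, c_dex, aggregability, shear,
                                        gain = 0.6, c_peak = 15,
                                        shear_half = 50) {
  stopifnot(all(hct >= 0), all(hct < 1), all(c_dex >= 0),
            all(aggregability >= 0), all(aggregability <= 1),
            all(shear >= 0))
  f_dex <- (c_dex / c_peak) * exp(1 - c_dex / c_peak)
  g_shear <- 1 / (1 + shear / shear_half)
  pmin(pmax(gain * aggregability * f_dex * (1 - hct) * g_shear, 0), 0.5)
}
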