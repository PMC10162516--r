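# Lumped-parameter virtual subject: a ventilated, insufflated pig that
# closes the loop in place of the animal.
#
# CO2 kinetics use two well-mixed pools. A fast arterial/alveolar pool
# (stiffness k_store, kPa per mL of CO2) receives peritoneal uptake and
# exchanges with a large tissue store (stiffness k_tissue) at conductance
# d_tissue; metabolic production enters the tissue pool. Elimination from
# the fast pool is alveolar ventilation times the alveolar CO2 fraction
# PaCO2 / pb_dry. The split gives the two time scales seen at the bedside:
# a brisk end-tidal response to rate changes and breath holds, on top of a
# slowly charging whole-body store. At steady state the expired CO2 volume
# rate equals metabolic production plus peritoneal uptake exactly.
#
# Oxygen is a single pool relaxing toward an alveolar-gas/shunt target set
# by FiO2 and PaCO2 (alveolar gas equation, respiratory quotient 0.8);
# during apnea it relaxes toward a fixed apneic tension instead.

#' Virtual subject parameters
#'
#' Constants of the lumped-parameter physiological model. Defaults describe
#' a ~21.5 kg anesthetized pig and are calibrated so the closed-loop
#' platform reproduces its design behavior: end-tidal CO2 pulled back to
#' target within each 3-minute stabilization window of the insufflation
#' staircase, modest (< 1 kPa) end-tidal rise per 20 s breath hold, and a
#' peak inspiratory pressure that climbs directly with intra-abdominal
#' pressure.
#'
#' @param weight Body weight, kg.
#' @param vco2_met Metabolic CO2 production, mL/min STPD.
#' @param vd Anatomical + apparatus dead space, mL.
#' @param k_store Fast (arterial/alveolar) CO2 pool stiffness, kPa/mL:
#'   the inverse of its effective capacitance.
#' @param k_tissue Tissue CO2 store stiffness, kPa/mL. The tissue store is
#'   much larger than the fast pool (`k_tissue << k_store`).
#' @param d_tissue Tissue-blood CO2 exchange conductance, mL/min/kPa.
#' @param k_perit Peritoneal CO2 uptake coefficient, mL/min per hPa of
#'   intra-abdominal pressure.
#' @param pb_dry Barometric minus water-vapour pressure, kPa; converts
#'   alveolar CO2 tension to a dry gas fraction.
#' @param crs0 Respiratory-system compliance at IAP 0, mL/hPa.
#' @param k_crs Relative compliance attenuation per unit IAP, 1/hPa:
#'   compliance at pressure `iap` is `crs0 / (1 + k_crs * iap)`.
#' @param shunt Venous admixture fraction in (0, 1).
#' @param o2_tau Time constant of the PaO2 pool, s.
#' @param pao2_hold Apneic PaO2 relaxation target during breath holds, mmHg.
#' @param pao2_ori_lo,pao2_ori_hi PaO2 endpoints (mmHg) of the linear
#'   oxygen-reserve-index mapping: ORI is 0 at `pao2_ori_lo`, 1 at
#'   `pao2_ori_hi`, clamped outside.
#' @param et_gradient PaCO2 minus end-tidal CO2 offset, kPa.
#' @param iap_ramp_rate Insufflator actuation slew rate, hPa/s.
#' @param noise_sd Named per-channel Gaussian noise standard deviations for
#'   `etco2` (kPa), `spo2` (%), `ori`, `pip` (hPa), `map_art` (mmHg),
#'   `cvp` (mmHg) and `heart_rate` (bpm).
#' @return A `subject_params` list.
#' @export
subject_params <- function(weight = 21.5,
                           vco2_met = 90,
                           vd = 100,
                           k_store = 0.025,
                           k_tissue = 5e-4,
                           d_tissue = 45,
                           k_perit = 1.0,
                           pb_dry = 95,
                           crs0 = 20,
                           k_crs = 0.05,
                           shunt = 0.07,
                           o2_tau = 45,
                           pao2_hold = 85,
                           pao2_ori_lo = 100,
                           pao2_ori_hi = 200,
                           et_gradient = 0.5,
                           iap_ramp_rate = 5,
                           noise_sd = c(
                             etco2 = 0.05, spo2 = 0.1, ori = 0.005, pip = 0.2,
                             map_art = 1.5, cvp = 0.5, heart_rate = 1.0
                           )) {
  p <- list(
    weight = weight, vco2_met = vco2_met, vd = vd, k_store = k_store,
    k_tissue = k_tissue, d_tissue = d_tissue, k_perit = k_perit,
    pb_dry = pb_dry, crs0 = crs0, k_crs = k_crs, shunt = shunt,
    o2_tau = o2_tau, pao2_hold = pao2_hold,
    pao2_ori_lo = pao2_ori_lo, pao2_ori_hi = pao2_ori_hi,
    et_gradient = et_gradient, iap_ramp_rate = iap_ramp_rate,
    noise_sd = noise_sd
  )
  pos <- c(
    "weight", "vco2_met", "vd", "k_store", "k_tissue", "d_tissue",
    "pb_dry", "crs0", "k_crs", "o2_tau", "pao2_hold", "iap_ramp_rate"
  )
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      abort(sprintf("`%s` must be positive.", f), class = "insuvent_validation_error")
    }
  }
  if (p$k_perit < 0) abort("`k_perit` must be non-negative.", class = "insuvent_validation_error")
  if (p$shunt < 0 || p$shunt >= 1) {
    abort("`shunt` must lie in [0, 1).", class = "insuvent_validation_error")
  }
  if (p$pao2_ori_lo >= p$pao2_ori_hi) {
    abort("`pao2_ori_lo` must be below `pao2_ori_hi`.", class = "insuvent_validation_error")
  }
  if (any(p$noise_sd < 0)) abort("`noise_sd` must be non-negative.", class = "insuvent_validation_error")
  structure(p, class = "subject_params")
}

#' Alveolar ventilation delivered by the current settings
#'
#' Minute alveolar ventilation is respiratory rate times the tidal volume in
#' excess of dead space; it is zero during a breath hold.
#'
#' @param vent A [ventilator_settings()] record.
#' @param params A [subject_params()] record.
#' @param breath_hold Logical; ventilation is paused during holds.
#' @return Alveolar ventilation in mL/min.
#' @export
alveolar_ventilation <- function(vent, params, breath_hold = FALSE) {
  if (vent$vt <= params$vd) {
    abort(
      sprintf(
        "Tidal volume (%g mL) does not exceed dead space (%g mL): total dead-space ventilation.",
        vent$vt, params$vd
      ),
      class = "insuvent_simulation_error"
    )
  }
  if (isTRUE(breath_hold)) {
    return(0)
  }
  vent$rr * (vent$vt - params$vd)
}

#' Total CO2 load entering the circulation
#'
#' The sum of metabolic CO2 production and peritoneal uptake of insufflated
#' CO2, the latter proportional to intra-abdominal pressure.
#'
#' @param iap Intra-abdominal pressure, hPa.
#' @param params A [subject_params()] record.
#' @return CO2 load in mL/min.
#' @export
co2_load <- function(iap, params) {
  if (any(iap < 0)) abort("`iap` must be non-negative.", class = "insuvent_validation_error")
  params$vco2_met + params$k_perit * iap
}

#' Subject state at a simulated instant
#'
#' @param paco2 Arterial CO2 tension, kPa.
#' @param pt_co2 Tissue-store CO2 tension, kPa.
#' @param pao2 Arterial O2 tension, mmHg.
#' @param time Seconds since run start.
#' @param iap_actual Achieved intra-abdominal pressure, hPa.
#' @param breath_hold_active Logical.
#' @return A `subject_state` list.
#' @export
subject_state <- function(paco2, pt_co2, pao2, time = 0, iap_actual = 0,
                          breath_hold_active = FALSE) {
  if (paco2 <= 0 || pao2 <= 0) {
    abort("`paco2` and `pao2` must be positive.", class = "insuvent_validation_error")
  }
  structure(
    list(
      paco2 = paco2, pt_co2 = pt_co2, pao2 = pao2, time = time,
      iap_actual = iap_actual, breath_hold_active = isTRUE(breath_hold_active)
    ),
    class = "subject_state"
  )
}

# arterial O2 relaxation target under ventilation: alveolar gas equation
# (respiratory quotient 0.8) reduced by the shunt fraction. mmHg.
.pao2_target <- function(fio2, paco2, params) {
  paco2_mmhg <- convert_pressure(paco2 * 10, "hPa", "mmHg") # kPa -> hPa -> mmHg
  pao2_alv <- fio2 / 100 * convert_pressure(params$pb_dry * 10, "hPa", "mmHg") -
    paco2_mmhg / 0.8
  (1 - params$shunt) * pao2_alv
}

#' Steady-state subject state for fixed settings
#'
#' Closed-form equilibrium of the gas-exchange model: arterial CO2 tension
#' `load * pb_dry / VA`, tissue tension offset by `vco2_met / d_tissue`, and
#' PaO2 at its alveolar-gas/shunt target.
#'
#' @param params A [subject_params()] record.
#' @param vent A [ventilator_settings()] record.
#' @param iap Intra-abdominal pressure, hPa (default 0).
#' @return A [subject_state()] at equilibrium.
#' @export
initial_subject_state <- function(params = subject_params(),
                                  vent = ventilator_settings(), iap = 0) {
  va <- alveolar_ventilation(vent, params)
  paco2 <- co2_load(iap, params) * params$pb_dry / va
  pt_co2 <- paco2 + params$vco2_met / params$d_tissue
  pao2 <- .pao2_target(vent$fio2, paco2, params)
  subject_state(paco2, pt_co2, pao2, time = 0, iap_actual = iap)
}

# time derivatives of (paco2, pt_co2) in kPa/s for fixed inputs
.co2_deriv <- function(paco2, pt_co2, va, iap, params) {
  exchange <- params$d_tissue * (pt_co2 - paco2) # tissue -> blood, mL/min
  elimination <- va * paco2 / params$pb_dry # expired, mL/min
  c(
    params$k_store * (exchange + params$k_perit * iap - elimination) / 60,
    params$k_tissue * (params$vco2_met - exchange) / 60
  )
}

#' Advance the subject state by one time step
#'
#' Integrates the two-pool CO2 model with a fixed-step explicit fourth-order
#' Runge-Kutta scheme and the PaO2 pool with its exact exponential update;
#' the achieved intra-abdominal pressure ramps toward the insufflator
#' setpoint at the configured slew rate.
#'
#' @param state A [subject_state()].
#' @param params A [subject_params()] record.
#' @param vent A [ventilator_settings()] record.
#' @param insuff An [insufflator_settings()] record.
#' @param dt Time step, s.
#' @param breath_hold Logical; pauses ventilation and switches the PaO2
#'   target to the apneic tension.
#' @return The advanced [subject_state()].
#' @export
advance_subject <- function(state, params, vent, insuff, dt = 1,
                            breath_hold = FALSE) {
  if (dt <= 0) abort("`dt` must be positive.", class = "insuvent_validation_error")
  setpoint <- if (insuff$enabled) insuff$iap_setpoint else 0
  max_move <- params$iap_ramp_rate * dt
  iap <- state$iap_actual + max(min(setpoint - state$iap_actual, max_move), -max_move)

  va <- alveolar_ventilation(vent, params, breath_hold = breath_hold)
  y <- c(state$paco2, state$pt_co2)
  k1 <- .co2_deriv(y[1], y[2], va, iap, params)
  k2 <- .co2_deriv(y[1] + dt / 2 * k1[1], y[2] + dt / 2 * k1[2], va, iap, params)
  k3 <- .co2_deriv(y[1] + dt / 2 * k2[1], y[2] + dt / 2 * k2[2], va, iap, params)
  k4 <- .co2_deriv(y[1] + dt * k3[1], y[2] + dt * k3[2], va, iap, params)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

  pao2_inf <- if (breath_hold) params$pao2_hold else .pao2_target(vent$fio2, y[1], params)
  pao2 <- pao2_inf + (state$pao2 - pao2_inf) * exp(-dt / params$o2_tau)

  if (any(!is.finite(c(y, pao2, iap)))) {
    abort(
      sprintf(
        "Non-finite subject state at t = %g s (paco2 %g, pt_co2 %g, pao2 %g).",
        state$time + dt, y[1], y[2], pao2
      ),
      class = "insuvent_simulation_error"
    )
  }
  subject_state(y[1], y[2], pao2,
    time = state$time + dt, iap_actual = iap,
    breath_hold_active = isTRUE(breath_hold)
  )
}

#' Oxygen saturation of hemoglobin from PaO2
#'
#' Severinghaus' empirical fit of the human oxyhemoglobin dissociation
#' curve, in percent.
#'
#' @param pao2 Arterial O2 tension, mmHg.
#' @return SpO2 in percent.
#' @export
severinghaus_spo2 <- function(pao2) {
  100 / (1 + 23400 / (pao2^3 + 150 * pao2))
}

#' Observe the monitored vital signs of the subject
#'
#' Produces one time-stamped multi-signal sample: end-tidal CO2 (arterial
#' tension minus a fixed gradient), pulse-oximetry saturation via the
#' Severinghaus curve, the oxygen reserve index as a clamped linear map of
#' PaO2, and the peak inspiratory pressure implied by the IAP-attenuated
#' respiratory-system compliance. During a breath hold the airway reads the
#' held pressure (PEEP for an expiratory hold, PEEP plus the tidal
#' inflation for an inspiratory hold) and the end-tidal channel is flagged
#' not valid. Blood pressures and heart rate are emitted as descriptive
#' signals only. Optional Gaussian noise is drawn from `noise_rng`.
#'
#' @param state A [subject_state()].
#' @param params A [subject_params()] record.
#' @param vent A [ventilator_settings()] record.
#' @param insuff An [insufflator_settings()] record.
#' @param hold_phase `NA` outside holds, otherwise `"expiratory"` or
#'   `"inspiratory"`.
#' @param noise_rng `NULL` for noise-free observation, otherwise a noise
#'   stream from [make_noise_streams()].
#' @return A one-row tibble (one vital sample).
#' @export
observe_subject <- function(state, params, vent, insuff,
                            hold_phase = NA_character_, noise_rng = NULL) {
  as_tibble(.observe_raw(state, params, vent, insuff, hold_phase, noise_rng))
}

# list-returning observation core; the simulation engine uses this directly
# to avoid per-tick tibble construction.
.observe_raw <- function(state, params, vent, insuff,
                         hold_phase = NA_character_, noise_rng = NULL) {
  in_hold <- !is.na(hold_phase)
  crs <- params$crs0 / (1 + params$k_crs * state$iap_actual)
  pip <- if (!in_hold) {
    vent$peep + vent$vt / crs
  } else if (identical(hold_phase, "inspiratory")) {
    vent$peep + vent$vt / crs
  } else {
    vent$peep
  }
  etco2 <- max(state$paco2 - params$et_gradient, 0)
  spo2 <- severinghaus_spo2(state$pao2)
  ori <- min(max(
    (state$pao2 - params$pao2_ori_lo) /
      (params$pao2_ori_hi - params$pao2_ori_lo), 0
  ), 1)
  map_art <- 70 + 0.8 * state$iap_actual
  cvp <- 5 + 0.3 * state$iap_actual
  heart_rate <- 90

  if (!is.null(noise_rng)) {
    sd <- params$noise_sd
    etco2 <- max(etco2 + draw_noise(noise_rng, "etco2", sd[["etco2"]]), 0)
    spo2 <- min(max(spo2 + draw_noise(noise_rng, "spo2", sd[["spo2"]]), 0), 100)
    ori <- min(max(ori + draw_noise(noise_rng, "ori", sd[["ori"]]), 0), 1)
    pip <- pip + draw_noise(noise_rng, "pip", sd[["pip"]])
    map_art <- map_art + draw_noise(noise_rng, "map_art", sd[["map_art"]])
    cvp <- cvp + draw_noise(noise_rng, "cvp", sd[["cvp"]])
    heart_rate <- heart_rate + draw_noise(noise_rng, "heart_rate", sd[["heart_rate"]])
  }

  list(
    timestamp = state$time,
    etco2 = etco2,
    spo2 = spo2,
    ori = ori,
    pip = pip,
    paco2 = state$paco2,
    pao2 = state$pao2,
    map_art = map_art,
    cvp = cvp,
    heart_rate = heart_rate,
    iap = state$iap_actual,
    hold = in_hold,
    hold_phase = hold_phase,
    valid = TRUE
  )
}

#' Per-channel reproducible noise streams
#'
#' One global seed feeds independent per-channel substreams, so enabling or
#' disabling one noise channel never perturbs the draws of another.
#'
#' @param seed Integer seed; `NULL` leaves the streams unseeded (drawn from
#'   fresh entropy).
#' @param channels Character vector of channel names.
#' @return An environment holding one RNG state per channel.
#' @export
make_noise_streams <- function(seed = NULL,
                               channels = c(
                                 "etco2", "spo2", "ori", "pip",
                                 "map_art", "cvp", "heart_rate"
                               )) {
  rng <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  for (i in seq_along(channels)) {
    if (!is.null(seed)) {
      set.seed((as.integer(seed) + 97L * i) %% .Machine$integer.max)
    } else {
      set.seed(NULL)
    }
    assign(channels[i], get(".Random.seed", globalenv()), envir = rng)
  }
  rng
}

#' Draw one Gaussian deviate from a named channel substream
#'
#' @param rng A stream environment from [make_noise_streams()].
#' @param channel Channel name.
#' @param sd Standard deviation; `sd = 0` returns 0 without consuming the
#'   stream.
#' @return A single numeric deviate.
#' @export
draw_noise <- function(rng, channel, sd) {
  if (sd == 0) {
    return(0)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(channel, envir = rng), envir = globalenv())
  x <- rnorm(1, 0, sd)
  assign(channel, get(".Random.seed", globalenv()), envir = rng)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  x
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<subject_params> %g kg | VCO2 %g mL/min | Vd %g mL | k_perit %g mL/min/hPa\n",
      "  CO2 pools: k_store %g, k_tissue %g kPa/mL, exchange %g mL/min/kPa\n",
      "  mechanics: Crs0 %g mL/hPa, k_crs %g /hPa | shunt %g | et gradient %g kPa\n"
    ),
    x$weight, x$vco2_met, x$vd, x$k_perit, x$k_store, x$k_tissue, x$d_tissue,
    x$crs0, x$k_crs, x$shunt, x$et_gradient
  ))
  invisible(x)
}

#' @export
print.subject_state <- function(x, ...) {
  cat(sprintf(
    "<subject_state> t %g s | PaCO2 %.2f kPa | PaO2 %.1f mmHg | IAP %.1f hPa%s\n",
    x$time, x$paco2, x$pao2, x$iap_actual,
    if (x$breath_hold_active) " | breath hold" else ""
  ))
  invisible(x)
}
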