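# Closed-loop controller: conditions the monitored signals, then
# independently titrates respiratory rate toward the end-tidal CO2 target
# and FiO2 toward the SpO2 / oxygen-reserve-index bands at a fixed
# execution interval, halting actuation during breath holds.

#' Closed-loop controller configuration
#'
#' All targets, bands, step sizes, limits and timing of the control
#' algorithm. Defaults reproduce the pilot configuration: permissive
#' hypercapnia with a 7.0 kPa end-tidal CO2 target, respiratory rate
#' adapted by 1 bpm per 40 s cycle within the 4-37 bpm hardware range with
#' a 10 bpm safety floor, FiO2 adapted by 1% to keep SpO2 at or above 97%
#' while holding the oxygen reserve index inside 0.0-0.4.
#'
#' @param etco2_target End-tidal CO2 target, kPa.
#' @param etco2_deadband Half-width of the no-action band around the
#'   target, kPa. The pilot configuration states a target only; the
#'   deadband keeps the rate from limit-cycling between adjacent settings.
#' @param rr_step Respiratory-rate increment per cycle, bpm.
#' @param rr_min_hw,rr_max_hw Ventilator hardware range, bpm.
#' @param rr_min_safety Active lower safety limit, bpm.
#' @param fio2_step FiO2 increment per cycle, percent.
#' @param spo2_band_lo,spo2_band_hi SpO2 band (percent) in which FiO2 is
#'   raised while the reserve index is inside its band.
#' @param spo2_min Minimum allowed SpO2, percent; below it FiO2 is raised
#'   regardless of the reserve index.
#' @param ori_lo,ori_hi Oxygen-reserve-index band.
#' @param interval Controller execution interval, s.
#' @param avg_window Measurement averaging window, s.
#' @return A `controller_config` list.
#' @export
controller_config <- function(etco2_target = 7.0,
                              etco2_deadband = 0.2,
                              rr_step = 1,
                              rr_min_hw = 4,
                              rr_max_hw = 37,
                              rr_min_safety = 10,
                              fio2_step = 1,
                              spo2_band_lo = 97,
                              spo2_band_hi = 98,
                              spo2_min = 97,
                              ori_lo = 0.0,
                              ori_hi = 0.4,
                              interval = 40,
                              avg_window = 5) {
  if (!(rr_min_hw <= rr_min_safety && rr_min_safety < rr_max_hw)) {
    abort("Require rr_min_hw <= rr_min_safety < rr_max_hw.",
      class = "insuvent_validation_error"
    )
  }
  if (spo2_band_lo > spo2_band_hi) {
    abort("Require spo2_band_lo <= spo2_band_hi.", class = "insuvent_validation_error")
  }
  if (ori_lo >= ori_hi) abort("Require ori_lo < ori_hi.", class = "insuvent_validation_error")
  if (interval <= 0 || avg_window <= 0) {
    abort("`interval` and `avg_window` must be positive.",
      class = "insuvent_validation_error"
    )
  }
  if (etco2_deadband < 0) {
    abort("`etco2_deadband` must be non-negative.", class = "insuvent_validation_error")
  }
  structure(
    list(
      etco2_target = etco2_target, etco2_deadband = etco2_deadband,
      rr_step = rr_step, rr_min_hw = rr_min_hw, rr_max_hw = rr_max_hw,
      rr_min_safety = rr_min_safety, fio2_step = fio2_step,
      spo2_band_lo = spo2_band_lo, spo2_band_hi = spo2_band_hi,
      spo2_min = spo2_min, ori_lo = ori_lo, ori_hi = ori_hi,
      interval = interval, avg_window = avg_window
    ),
    class = "controller_config"
  )
}

# per-channel physiologic validity; a sample must also carry valid = TRUE.
.channel_valid <- function(samples, channel) {
  x <- samples[[channel]]
  ok <- samples$valid & !is.na(x)
  ok <- ok & switch(channel,
    etco2 = x >= 0 & x <= 20 & !samples$hold,
    spo2 = x >= 50 & x <= 100,
    ori = x >= 0 & x <= 1
  )
  ok
}

#' Condition raw vital samples into a controller input
#'
#' Checks each sample for validity (source flag plus physiologic range:
#' end-tidal CO2 0-20 kPa, SpO2 50-100%, reserve index 0-1; the end-tidal
#' channel is additionally invalid during breath holds) and averages the
#' valid samples per channel over the window `(now - avg_window, now]`.
#' Staleness is signaled, never thrown.
#'
#' @param samples Time-ordered tibble of vital samples (columns
#'   `timestamp`, `etco2`, `spo2`, `ori`, `hold`, `valid`).
#' @param now Current time, s.
#' @param cfg A [controller_config()].
#' @return A one-row tibble with `etco2_avg`, `spo2_avg`, `ori_avg`,
#'   `breath_hold` (hold active at `now`) and `stale` (no valid sample of
#'   any channel in the window).
#' @export
condition_measurements <- function(samples, now, cfg = controller_config()) {
  w <- samples[samples$timestamp > now - cfg$avg_window & samples$timestamp <= now, ]
  ch_mean <- function(channel) {
    ok <- .channel_valid(w, channel)
    if (!any(ok)) NA_real_ else mean(w[[channel]][ok])
  }
  etco2_avg <- ch_mean("etco2")
  spo2_avg <- ch_mean("spo2")
  ori_avg <- ch_mean("ori")
  at_now <- w[nrow(w), ]
  tibble(
    etco2_avg = etco2_avg,
    spo2_avg = spo2_avg,
    ori_avg = ori_avg,
    breath_hold = nrow(w) > 0 && isTRUE(at_now$hold),
    stale = all(is.na(c(etco2_avg, spo2_avg, ori_avg)))
  )
}

#' Carbon dioxide control branch
#'
#' Moves the respiratory rate one step toward the end-tidal CO2 target when
#' the conditioned measurement leaves the deadband, clamped to the hardware
#' range and the active safety floor. A missing (stale) measurement leaves
#' the rate unchanged.
#'
#' @param input Conditioned input from [condition_measurements()].
#' @param current_rr Current respiratory rate, bpm.
#' @param cfg A [controller_config()].
#' @return Commanded respiratory rate, bpm.
#' @export
co2_branch <- function(input, current_rr, cfg = controller_config()) {
  rr <- current_rr
  e <- input$etco2_avg
  if (!is.na(e)) {
    if (e > cfg$etco2_target + cfg$etco2_deadband) rr <- rr + cfg$rr_step
    if (e < cfg$etco2_target - cfg$etco2_deadband) rr <- rr - cfg$rr_step
  }
  min(max(rr, max(cfg$rr_min_hw, cfg$rr_min_safety)), cfg$rr_max_hw)
}

#' Oxygenation control branch
#'
#' Raises FiO2 one step when SpO2 sits in the working band with the oxygen
#' reserve index inside its band (building the hyperoxic buffer for breath
#' holds), or whenever SpO2 falls below the minimum allowed level (hypoxia
#' protection dominates any reserve-index reading); lowers FiO2 one step
#' when the reserve index exceeds its band. Clamped to 21-100%.
#'
#' @param input Conditioned input from [condition_measurements()].
#' @param current_fio2 Current FiO2, percent.
#' @param cfg A [controller_config()].
#' @return Commanded FiO2, percent.
#' @export
o2_branch <- function(input, current_fio2, cfg = controller_config()) {
  fio2 <- current_fio2
  s <- input$spo2_avg
  o <- input$ori_avg
  if (!is.na(s) && s < cfg$spo2_min) {
    fio2 <- fio2 + cfg$fio2_step
  } else if (!is.na(s) && !is.na(o) &&
    s >= cfg$spo2_band_lo && s <= cfg$spo2_band_hi &&
    o >= cfg$ori_lo && o <= cfg$ori_hi) {
    fio2 <- fio2 + cfg$fio2_step
  } else if (!is.na(o) && o > cfg$ori_hi) {
    fio2 <- fio2 - cfg$fio2_step
  }
  min(max(fio2, 21), 100)
}

#' Execute one control cycle
#'
#' Applies both control branches to the current ventilator settings. When a
#' breath hold is active or the input is stale the settings are returned
#' unchanged. Tidal volume, PEEP and inspiratory time are never modified.
#'
#' @param input Conditioned input from [condition_measurements()].
#' @param settings Current [ventilator_settings()].
#' @param cfg A [controller_config()].
#' @return The (possibly updated) [ventilator_settings()].
#' @export
control_cycle <- function(input, settings, cfg = controller_config()) {
  if (isTRUE(input$breath_hold) || isTRUE(input$stale)) {
    return(settings)
  }
  settings$rr <- co2_branch(input, settings$rr, cfg)
  settings$fio2 <- o2_branch(input, settings$fio2, cfg)
  settings
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<controller_config> etCO2 %g +/- %g kPa -> RR %+g bpm in [%g, %g] (floor %g)\n",
      "  SpO2 band %g-%g%% (min %g), ORI %g-%g -> FiO2 %+g%% | every %g s, %g s window\n"
    ),
    x$etco2_target, x$etco2_deadband, x$rr_step, x$rr_min_hw, x$rr_max_hw,
    x$rr_min_safety, x$spo2_band_lo, x$spo2_band_hi, x$spo2_min,
    x$ori_lo, x$ori_hi, x$fio2_step, x$interval, x$avg_window
  ))
  invisible(x)
}
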