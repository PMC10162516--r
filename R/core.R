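# Shared domain types, unit conversions and derived-settings arithmetic.
#
# All pressures are stored internally in hPa. Ventilation pressures are
# conventionally labelled in cmH2O at the bedside; 1 hPa = 1.019716 cmH2O is
# close enough to unity that device displays use the two interchangeably.
# convert_pressure() applies the exact factors; pressure_display_unit()
# implements the 1:1 hPa <-> cmH2O labelling convention used on plot axes.

.pressure_to_hpa <- c(hPa = 1, cmH2O = 1 / 1.019716, mmHg = 1 / 0.750062)

#' Convert a pressure between hPa, cmH2O and mmHg
#'
#' Exact physical conversion factors are used (1 hPa = 0.750062 mmHg =
#' 1.019716 cmH2O); rounding is left to display time. Values are vectorised.
#'
#' @param value Numeric vector of pressures.
#' @param from,to Units, each one of `"hPa"`, `"cmH2O"`, `"mmHg"`.
#' @return Numeric vector of pressures in `to` units.
#' @examples
#' convert_pressure(5, "hPa", "mmHg") # PEEP of 5 hPa ~ 3.75 mmHg
#' @export
convert_pressure <- function(value, from = "hPa", to = "hPa") {
  from <- match.arg(from, names(.pressure_to_hpa))
  to <- match.arg(to, names(.pressure_to_hpa))
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite numeric.", class = "insuvent_config_error")
  }
  value * .pressure_to_hpa[[from]] / .pressure_to_hpa[[to]]
}

#' Volume-guarantee tidal volume from body weight
#'
#' Computes weight x per-kg target and quantizes it to the ventilator's
#' setting grid, rounding to the nearest multiple of `resolution` with ties
#' toward the lower volume (the conservative choice for lung-protective
#' ventilation).
#'
#' @param weight Body weight in kg.
#' @param per_kg_target Target tidal volume in mL/kg (default 7.5).
#' @param resolution Ventilator setting grid in mL (default 10).
#' @return Tidal volume setting in mL.
#' @examples
#' tidal_volume_setting(21.5) # 161.25 mL -> 160 mL on a 10 mL grid
#' @export
tidal_volume_setting <- function(weight, per_kg_target = 7.5, resolution = 10) {
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    abort("`weight` must be a single positive number.", class = "insuvent_validation_error")
  }
  if (per_kg_target <= 0 || resolution <= 0) {
    abort("`per_kg_target` and `resolution` must be positive.",
      class = "insuvent_validation_error"
    )
  }
  raw <- weight * per_kg_target
  lower <- floor(raw / resolution) * resolution
  upper <- lower + resolution
  if (raw - lower <= upper - raw) lower else upper
}

#' Ventilator settings record
#'
#' The actuator command set for a volume-guarantee ventilator: tidal volume,
#' respiratory rate, PEEP, inspired oxygen fraction and inspiratory time.
#' The closed-loop controller only ever modifies `rr` and `fio2`; the other
#' fields are fixed for the duration of an experiment.
#'
#' @param vt Tidal volume in mL (must be positive).
#' @param rr Respiratory rate in breaths/min.
#' @param peep Positive end-expiratory pressure in hPa.
#' @param fio2 Inspired oxygen fraction in percent, 21-100.
#' @param ti Inspiratory time in seconds.
#' @param volume_guarantee Logical; volume-guarantee mode flag.
#' @param rr_range Permitted hardware range for `rr` (breaths/min).
#' @return A `ventilator_settings` list.
#' @export
ventilator_settings <- function(vt = 160, rr = 20, peep = 5, fio2 = 30,
                                ti = 0.8, volume_guarantee = TRUE,
                                rr_range = c(4, 37)) {
  if (vt <= 0) abort("`vt` must be positive.", class = "insuvent_validation_error")
  if (rr < rr_range[1] || rr > rr_range[2]) {
    abort(sprintf("`rr` must lie in the hardware range [%g, %g].", rr_range[1], rr_range[2]),
      class = "insuvent_validation_error"
    )
  }
  if (fio2 < 21 || fio2 > 100) {
    abort("`fio2` must lie in [21, 100] percent.", class = "insuvent_validation_error")
  }
  if (ti <= 0) abort("`ti` must be positive.", class = "insuvent_validation_error")
  structure(
    list(
      vt = vt, rr = rr, peep = peep, fio2 = fio2, ti = ti,
      volume_guarantee = isTRUE(volume_guarantee), rr_range = rr_range
    ),
    class = "ventilator_settings"
  )
}

#' Insufflator settings record
#'
#' @param iap_setpoint Commanded intra-abdominal pressure in hPa.
#' @param enabled Logical; whether insufflation is active.
#' @param iap_max Configured maximum setpoint in hPa (default 20).
#' @return An `insufflator_settings` list.
#' @export
insufflator_settings <- function(iap_setpoint = 0, enabled = TRUE, iap_max = 20) {
  if (iap_setpoint < 0 || iap_setpoint > iap_max) {
    abort(sprintf("`iap_setpoint` must lie in [0, %g] hPa.", iap_max),
      class = "insuvent_validation_error"
    )
  }
  structure(
    list(iap_setpoint = iap_setpoint, enabled = isTRUE(enabled), iap_max = iap_max),
    class = "insufflator_settings"
  )
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf(
    "<ventilator_settings> Vt %g mL | RR %g bpm | PEEP %g hPa | FiO2 %g%% | Ti %g s%s\n",
    x$vt, x$rr, x$peep, x$fio2, x$ti,
    if (x$volume_guarantee) " | volume guarantee" else ""
  ))
  invisible(x)
}

#' @export
print.insufflator_settings <- function(x, ...) {
  cat(sprintf(
    "<insufflator_settings> IAP setpoint %g hPa (%s)\n",
    x$iap_setpoint, if (x$enabled) "enabled" else "disabled"
  ))
  invisible(x)
}
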