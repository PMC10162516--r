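# Post-run analysis and visualization: per-step settling metrics,
# pressure-interaction summaries, and multi-panel time-series figures.

# first hold onset within a step, or the step end when it has no holds
.step_bounds <- function(log, step_label) {
  idx <- which(log$step == step_label)
  if (!length(idx)) {
    abort(sprintf("Unknown step label: %s", step_label), class = "insuvent_config_error")
  }
  hold_idx <- idx[log$hold[idx]]
  list(
    start = idx[1],
    hold_onset = if (length(hold_idx)) hold_idx[1] else idx[length(idx)],
    end = idx[length(idx)]
  )
}

#' Settling time of end-tidal CO2 within a protocol step
#'
#' The time from the step's insufflation command to the first instant at
#' which end-tidal CO2 enters the band `target +/- band` and remains inside
#' it until the onset of the step's first breath hold. `NA` (not settled)
#' if it never does.
#'
#' @param log An `insu_run_log`.
#' @param step_label Step label present in the log.
#' @param target End-tidal CO2 target, kPa.
#' @param band Half-width of the settling band, kPa. The platform reports
#'   settling against a 0.3 kPa band by default; the controller deadband is
#'   tighter.
#' @return Settling time in seconds, or `NA` if not settled.
#' @export
settling_time <- function(log, step_label, target = 7.0, band = 0.3) {
  b <- .step_bounds(log, step_label)
  idx <- b$start:b$hold_onset
  idx <- idx[!log$hold[idx]]
  et <- log$etco2[idx]
  inband <- abs(et - target) <= band
  if (!length(inband) || !inband[length(inband)]) {
    return(NA_real_)
  }
  r <- rle(rev(inband))
  n_in <- r$lengths[1]
  t0 <- log$time[b$start]
  entry <- log$time[idx[length(idx) - n_in + 1]]
  entry - t0
}

#' Per-step summary of a protocol run
#'
#' One row per protocol step: the commanded IAP, the settling time of
#' end-tidal CO2 (see [settling_time()]), and end-tidal CO2, peak
#' inspiratory pressure, respiratory rate and FiO2 at the hold onset (the
#' last ventilated tick before the step's first breath hold).
#'
#' @inheritParams settling_time
#' @return A tibble with one row per step.
#' @export
step_summary <- function(log, target = 7.0, band = 0.3) {
  steps <- unique(log$step)
  rows <- purrr::map(steps, function(s) {
    b <- .step_bounds(log, s)
    idx <- b$start:b$hold_onset
    vent_idx <- idx[!log$hold[idx]]
    at <- vent_idx[length(vent_idx)]
    st <- settling_time(log, s, target, band)
    tibble(
      step_label = s,
      iap = log$iap_set[b$start],
      settling_time = st,
      settled = !is.na(st),
      etco2_at_hold = log$etco2[at],
      pip_at_hold = log$pip[at],
      rr_at_hold = log$rr[at],
      fio2_at_hold = log$fio2[at]
    )
  })
  out <- bind_rows(rows)
  attr(out, "target") <- target
  attr(out, "band") <- band
  out
}

#' Peak inspiratory pressure against intra-abdominal pressure
#'
#' One row per plateau with the commanded IAP and the peak inspiratory
#' pressure at the hold onset; under volume guarantee with fixed PEEP this
#' is the direct readout of the compliance lost to insufflation.
#'
#' @param log An `insu_run_log`.
#' @return A tibble with columns `step_label`, `iap`, `pip_at_hold`.
#' @export
pip_vs_iap <- function(log) {
  step_summary(log) %>% select("step_label", "iap", "pip_at_hold")
}

.shade_holds <- function(log) {
  if (!any(log$hold)) {
    return(NULL)
  }
  runs <- rle(log$hold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hold_runs <- which(runs$values)
  shades <- tibble(
    xmin = log$time[starts[hold_runs]],
    xmax = log$time[ends[hold_runs]]
  )
  ggplot2::geom_rect(
    data = shades,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
    inherit.aes = FALSE, fill = "grey80", alpha = 0.6
  )
}

#' Multi-panel time-series plot of a run
#'
#' Four stacked panels: (A) commanded and achieved insufflation pressure;
#' (B) end-tidal CO2 with the commanded respiratory rate; (C) SpO2, oxygen
#' reserve index and FiO2; (D) airway pressures, labelled in cmH2O on the
#' left axis and mmHg on the right. Breath holds are shaded grey.
#'
#' @param object An `insu_run_log`.
#' @param ... Unused.
#' @return A patchwork of ggplot panels.
#' @export
autoplot.insu_run_log <- function(object, ...) {
  log <- as_tibble(object)
  if (nrow(log) == 0) {
    abort("Cannot plot an empty run log.", class = "insuvent_validation_error")
  }
  shade <- .shade_holds(log)
  base <- function() ggplot2::ggplot(log, ggplot2::aes(x = .data$time / 60))

  p_a <- base() +
    shade +
    ggplot2::geom_step(ggplot2::aes(y = .data$iap_set), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$iap)) +
    ggplot2::labs(y = "IAP (hPa)", x = NULL, title = "A  Insufflation pressure")

  p_b <- base() +
    shade +
    ggplot2::geom_line(ggplot2::aes(y = .data$etco2)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$rr / 5), colour = "grey40") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . * 5, name = "RR (bpm)")
    ) +
    ggplot2::labs(y = "etCO2 (kPa)", x = NULL, title = "B  End-tidal CO2 and rate")

  p_c <- base() +
    shade +
    ggplot2::geom_line(ggplot2::aes(y = .data$spo2)) +
    ggplot2::geom_line(ggplot2::aes(y = 90 + 10 * .data$ori), colour = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$fio2 + 60), colour = "grey70") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ (. - 90) / 10, name = "ORI")
    ) +
    ggplot2::labs(y = "SpO2 (%) / FiO2+60", x = NULL, title = "C  Oxygenation")

  # ventilation pressures stored in hPa are labelled 1:1 in cmH2O (device
  # display convention); the right axis carries the exact mmHg conversion.
  p_d <- base() +
    shade +
    ggplot2::geom_line(ggplot2::aes(y = .data$pip)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$peep), linetype = "dotted") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ convert_pressure(., "hPa", "mmHg"),
        name = "Pressure (mmHg)"
      )
    ) +
    ggplot2::labs(
      y = "Pressure (cmH2O)", x = "Time (min)",
      title = "D  Airway pressures"
    )

  patchwork::wrap_plots(p_a, p_b, p_c, p_d, ncol = 1)
}

#' Render the run time-series panels to files
#'
#' Writes the four panels of [autoplot.insu_run_log()] as separate figure
#' files named `panel_a_iap`, `panel_b_co2`, `panel_c_o2`,
#' `panel_d_pressures`.
#'
#' @param log An `insu_run_log`.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @return Character vector of the files written, invisibly.
#' @export
render_timeseries <- function(log, out_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (nrow(log) == 0) {
    abort("Cannot render an empty run log.", class = "insuvent_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panels <- autoplot(log)
  names <- c("panel_a_iap", "panel_b_co2", "panel_c_o2", "panel_d_pressures")
  files <- file.path(out_dir, paste0(names, ".", format))
  for (i in seq_along(files)) {
    ggplot2::ggsave(files[i], panels[[i]], width = 8, height = 3, dpi = 120)
  }
  invisible(files)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
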