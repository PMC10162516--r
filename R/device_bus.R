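# Mock-device and recording layer: time-synchronized multi-stream run logs
# on a single monotone clock, CSV persistence with a configuration header,
# protocol-derived file naming, and controller replay from recorded logs.

.run_log_cols <- c(
  "time", "step", "iap_set", "iap", "etco2", "spo2", "ori", "pip",
  "paco2", "pao2", "map_art", "cvp", "heart_rate", "hold", "hold_phase",
  "valid", "rr", "fio2", "vt", "peep", "ti", "cmd", "override"
)

new_run_log <- function(records, header = list(), commands = NULL) {
  structure(
    records,
    class = c("insu_run_log", class(tibble())),
    header = header,
    commands = commands
  )
}

#' A mock device endpoint on the platform bus
#'
#' @param name Unique device name on the bus.
#' @param role One of `"ventilator"`, `"insufflator"`, `"monitor"`.
#' @param latency Command-to-effect delay, s (non-negative).
#' @return A `device_endpoint` list.
#' @export
device_endpoint <- function(name, role = c("ventilator", "insufflator", "monitor"),
                            latency = 0) {
  role <- match.arg(role)
  if (latency < 0) abort("`latency` must be non-negative.", class = "insuvent_validation_error")
  structure(
    list(name = name, role = role, latency = latency, last_seen = NA_real_),
    class = "device_endpoint"
  )
}

#' Assemble endpoints into a device bus
#'
#' @param ... `device_endpoint` objects; names must be unique.
#' @return A `device_bus` list of endpoints.
#' @export
device_bus <- function(...) {
  eps <- list(...)
  nm <- purrr::map_chr(eps, "name")
  if (anyDuplicated(nm)) {
    abort("Device names must be unique on a bus.", class = "insuvent_validation_error")
  }
  structure(setNames(eps, nm), class = "device_bus")
}

#' Append one record to a run log
#'
#' Enforces the single monotone clock: a timestamp earlier than the last
#' recorded one is a logging error.
#'
#' @param log An `insu_run_log` (or `NULL` to start one).
#' @param timestamp Seconds since run start.
#' @param step_label Protocol step label.
#' @param sample One-row tibble from [observe_subject()].
#' @param settings Current [ventilator_settings()].
#' @param iap_set Commanded insufflation pressure, hPa.
#' @param cmd Logical; a controller command was applied at this tick.
#' @param override Logical; the applied command came from a manual override.
#' @param header Header list, stored when the log is created.
#' @return The extended `insu_run_log`.
#' @export
log_record <- function(log, timestamp, step_label, sample, settings,
                       iap_set = NA_real_, cmd = FALSE, override = FALSE,
                       header = list()) {
  if (!is.null(log) && nrow(log) > 0 && timestamp < max(log$time)) {
    abort(
      sprintf(
        "Clock regression: record at t = %g s after t = %g s.",
        timestamp, max(log$time)
      ),
      class = "insuvent_logging_error"
    )
  }
  row <- tibble(
    time = timestamp, step = step_label, iap_set = iap_set,
    iap = sample$iap, etco2 = sample$etco2, spo2 = sample$spo2,
    ori = sample$ori, pip = sample$pip, paco2 = sample$paco2,
    pao2 = sample$pao2, map_art = sample$map_art, cvp = sample$cvp,
    heart_rate = sample$heart_rate, hold = sample$hold,
    hold_phase = sample$hold_phase, valid = sample$valid,
    rr = settings$rr, fio2 = settings$fio2, vt = settings$vt,
    peep = settings$peep, ti = settings$ti, cmd = cmd, override = override
  )
  if (is.null(log)) {
    new_run_log(row, header = header)
  } else {
    new_run_log(bind_rows(log, row),
      header = attr(log, "header"),
      commands = attr(log, "commands")
    )
  }
}

#' Protocol-derived run-log file name
#'
#' @param protocol_name Protocol name.
#' @param start Run start stamp (`POSIXct` or character).
#' @param step_label Optional step label for per-step artifacts.
#' @param ext File extension.
#' @return A file name of the form `protocol_[step_]stamp.ext`.
#' @export
run_log_filename <- function(protocol_name, start = Sys.time(),
                             step_label = NULL, ext = "csv") {
  stamp <- if (inherits(start, "POSIXt")) format(start, "%Y%m%dT%H%M%S") else as.character(start)
  parts <- c(protocol_name, step_label, stamp)
  paste0(paste(parts, collapse = "_"), ".", ext)
}

#' Write a run log to CSV
#'
#' The full configuration header is written once as `#`-prefixed comment
#' lines (the snapshot serialized as JSON) followed by one CSV row per
#' tick, wide format, fixed column order.
#'
#' @param log An `insu_run_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  header <- attr(log, "header")
  lines <- c(
    "# insuvent run log",
    paste0(
      "# header: ",
      jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")
    )
  )
  readr::write_lines(lines, path)
  readr::write_csv(as_tibble(log)[, .run_log_cols], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a run log written by [write_run_log()]
#'
#' @param path Path to the CSV file.
#' @return An `insu_run_log` with its header restored.
#' @export
read_run_log <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Run log not found: %s", path), class = "insuvent_config_error")
  }
  first <- readr::read_lines(path, n_max = 10)
  hline <- grep("^# header: ", first, value = TRUE)
  header <- if (length(hline)) {
    jsonlite::fromJSON(sub("^# header: ", "", hline[1]), simplifyVector = TRUE)
  } else {
    list()
  }
  # base read.csv: strtod parses doubles with correct rounding, so a written
  # log re-reads bit-exactly
  classes <- c(
    step = "character", hold_phase = "character", hold = "logical",
    valid = "logical", cmd = "logical", override = "logical"
  )
  rec <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cn in names(rec)) {
    rec[[cn]] <- if (cn %in% names(classes)) {
      switch(classes[[cn]],
        character = as.character(rec[[cn]]),
        logical = as.logical(rec[[cn]])
      )
    } else {
      as.numeric(rec[[cn]])
    }
  }
  rec <- as_tibble(rec)
  missing <- setdiff(.run_log_cols, names(rec))
  if (length(missing)) {
    abort(
      sprintf("Run log is missing column(s): %s", paste(missing, collapse = ", ")),
      class = "insuvent_parse_error"
    )
  }
  new_run_log(rec[, .run_log_cols], header = header)
}

#' Replay a recorded log through the controller
#'
#' Streams the recorded vital samples through measurement conditioning and
#' the control cycle at the configured interval, starting from the
#' ventilator settings recorded at the first tick, and emits the command
#' sequence. A live simulated run and a replay of its own log produce
#' identical command traces.
#'
#' @param log An `insu_run_log` or a path to a run-log CSV.
#' @param cfg A [controller_config()]; defaults to the configuration
#'   snapshot in the log header when present.
#' @param vent Initial [ventilator_settings()]; defaults to the settings
#'   recorded at the first tick.
#' @return A tibble of commands: `time`, `rr`, `fio2`.
#' @export
replay <- function(log, cfg = NULL, vent = NULL) {
  if (is.character(log)) log <- read_run_log(log)
  need <- c("time", "etco2", "spo2", "ori", "hold", "valid", "rr", "fio2")
  missing <- setdiff(need, names(log))
  if (length(missing)) {
    abort(
      sprintf("Replay input is missing column(s): %s", paste(missing, collapse = ", ")),
      class = "insuvent_parse_error"
    )
  }
  header <- attr(log, "header")
  if (is.null(cfg)) {
    cfg <- if (!is.null(header$controller)) {
      do.call(controller_config, header$controller[names(formals(controller_config))[
        names(formals(controller_config)) %in% names(header$controller)
      ]])
    } else {
      controller_config()
    }
  }
  if (is.null(vent)) {
    col1 <- function(cn, default) if (cn %in% names(log)) log[[cn]][1] else default
    vent <- ventilator_settings(
      vt = col1("vt", 160), rr = log$rr[1], peep = col1("peep", 5),
      fio2 = log$fio2[1], ti = col1("ti", 0.8)
    )
  }
  samples <- tibble(
    timestamp = log$time, etco2 = log$etco2, spo2 = log$spo2,
    ori = log$ori, hold = log$hold, valid = log$valid
  )
  t_end <- max(samples$timestamp)
  cycle_times <- seq(cfg$interval, t_end, by = cfg$interval)
  out_time <- numeric(0)
  out_rr <- numeric(0)
  out_fio2 <- numeric(0)
  for (tm in cycle_times) {
    input <- condition_measurements(samples, tm, cfg)
    if (!input$breath_hold && !input$stale) {
      vent <- control_cycle(input, vent, cfg)
      out_time <- c(out_time, tm)
      out_rr <- c(out_rr, vent$rr)
      out_fio2 <- c(out_fio2, vent$fio2)
    }
  }
  tibble(time = out_time, rr = out_rr, fio2 = out_fio2)
}

#' Command trace of a simulated run
#'
#' @param log An `insu_run_log` returned by [run_protocol()] or
#'   [run_closed_loop()].
#' @return Tibble of the applied controller commands (`time`, `rr`,
#'   `fio2`, `override`).
#' @export
run_commands <- function(log) {
  cmds <- attr(log, "commands")
  if (is.null(cmds)) {
    cmds <- as_tibble(log) %>%
      filter(.data$cmd) %>%
      select("time", "rr", "fio2", "override")
  }
  cmds
}

#' @export
print.insu_run_log <- function(x, ...) {
  h <- attr(x, "header")
  cat(sprintf(
    "<insu_run_log> %d records, %g s, protocol '%s', seed %s, noise %s\n",
    nrow(x), if (nrow(x)) max(x$time) else 0,
    h$protocol %||% "?", format(h$seed %||% NA), format(h$noise %||% NA)
  ))
  NextMethod()
}

#' Tidy and summarize run logs
#'
#' `tidy()` returns the plain per-tick records; `glance()` returns a
#' one-row summary of the run.
#'
#' @param x An `insu_run_log`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.insu_run_log <- function(x, ...) {
  as_tibble(unclass(x)[.run_log_cols])
}

#' @rdname tidy.insu_run_log
#' @export
glance.insu_run_log <- function(x, ...) {
  h <- attr(x, "header")
  tibble(
    protocol = h$protocol %||% NA_character_,
    duration = max(x$time),
    n_records = nrow(x),
    n_steps = length(unique(x$step)),
    n_commands = sum(x$cmd),
    max_iap_set = max(x$iap_set),
    min_spo2 = min(x$spo2),
    max_ori = max(x$ori),
    final_rr = last(x$rr),
    final_fio2 = last(x$fio2)
  )
}
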