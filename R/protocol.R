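# Experiment-protocol engine: the intra-abdominal pressure staircase with
# stabilization timers, paired expiratory/inspiratory breath holds at each
# plateau, step labelling and manual-override hooks.

#' One protocol step
#'
#' @param iap Intra-abdominal pressure setpoint for the step, hPa.
#' @param stabilization Stabilization time before the holds, s.
#' @param holds Tibble with columns `phase` (`"expiratory"` or
#'   `"inspiratory"`) and `duration` (s); one row per breath hold taken
#'   after the stabilization window.
#' @param label Step label; autogenerated by [as_protocol()] when `NA`.
#' @return A one-row tibble.
#' @export
protocol_step <- function(iap, stabilization = 180,
                          holds = tibble(
                            phase = c("expiratory", "inspiratory"),
                            duration = c(20, 20)
                          ),
                          label = NA_character_) {
  if (stabilization < 0) {
    abort("`stabilization` must be non-negative.", class = "insuvent_validation_error")
  }
  if (nrow(holds) > 0) {
    if (!all(holds$phase %in% c("expiratory", "inspiratory"))) {
      abort("Hold phases must be 'expiratory' or 'inspiratory'.",
        class = "insuvent_validation_error"
      )
    }
    if (any(holds$duration <= 0)) {
      abort("Hold durations must be positive.", class = "insuvent_validation_error")
    }
  }
  tibble(
    label = label, iap = iap, stabilization = stabilization,
    holds = list(holds)
  )
}

#' Assemble protocol steps into a protocol
#'
#' @param steps Tibble of steps (rows from [protocol_step()]).
#' @param name Protocol name, used in run-log file naming.
#' @return An `insu_protocol` tibble.
#' @export
as_protocol <- function(steps, name = "protocol") {
  if (nrow(steps) == 0) {
    abort("A protocol needs at least one step.", class = "insuvent_validation_error")
  }
  steps$label <- ifelse(
    is.na(steps$label),
    sprintf("s%02d_iap%02d", seq_len(nrow(steps)), round(steps$iap)),
    steps$label
  )
  structure(steps, class = c("insu_protocol", class(tibble())), name = name)
}

#' The default insufflation staircase protocol
#'
#' Thirteen steps at 0, 5, 8, 10, 12, 14, 16, 18, 20, 16, 10, 5 and 0 hPa,
#' each with a 3-minute stabilization window followed by one expiratory and
#' one inspiratory breath hold (20 s each, the CT acquisition pauses).
#'
#' @param stabilization Stabilization time per step, s.
#' @param hold_duration Duration of each breath hold, s.
#' @return An `insu_protocol` tibble with 13 rows.
#' @export
default_protocol <- function(stabilization = 180, hold_duration = 20) {
  iaps <- c(0, 5, 8, 10, 12, 14, 16, 18, 20, 16, 10, 5, 0)
  steps <- purrr::map(iaps, function(p) {
    protocol_step(p,
      stabilization = stabilization,
      holds = tibble(
        phase = c("expiratory", "inspiratory"),
        duration = c(hold_duration, hold_duration)
      )
    )
  })
  as_protocol(bind_rows(steps), name = "iap_staircase")
}

#' Read a protocol definition from a YAML file
#'
#' The file holds `name` and a list of `steps`, each with `iap`,
#' `stabilization` and a `holds` list of `{phase, duration}` entries. A
#' file whose top level is the string `default` (or has `default: true`)
#' loads the built-in staircase.
#'
#' @param path Path to the YAML file.
#' @return An `insu_protocol` tibble.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Protocol file not found: %s", path), class = "insuvent_config_error")
  }
  y <- yaml::read_yaml(path)
  if (identical(y, "default") || isTRUE(y$default)) {
    return(default_protocol())
  }
  if (is.null(y$steps)) {
    abort("Protocol file has no `steps` entry.", class = "insuvent_config_error")
  }
  steps <- purrr::map(y$steps, function(s) {
    holds <- if (is.null(s$holds)) {
      tibble(phase = character(), duration = numeric())
    } else {
      bind_rows(purrr::map(s$holds, tibble::as_tibble_row))
    }
    protocol_step(s$iap,
      stabilization = s$stabilization %||% 180,
      holds = holds,
      label = s$label %||% NA_character_
    )
  })
  as_protocol(bind_rows(steps), name = y$name %||% "protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand a protocol into a per-tick schedule: time, step label, IAP
# setpoint and hold phase. Each hold is followed by `hold_recovery` seconds
# of resumed ventilation within the same step, so holds extend the step
# beyond its stabilization window.
.build_schedule <- function(protocol, dt, hold_recovery) {
  segs <- purrr::pmap(
    list(protocol$label, protocol$iap, protocol$stabilization, protocol$holds),
    function(label, iap, stab, holds) {
      dur <- c(stab)
      phase <- c(NA_character_)
      for (j in seq_len(nrow(holds))) {
        dur <- c(dur, holds$duration[j], hold_recovery)
        phase <- c(phase, holds$phase[j], NA_character_)
      }
      tibble(label = label, iap = iap, dur = dur, phase = phase)
    }
  )
  segs <- bind_rows(segs)
  segs <- segs[segs$dur > 0, ]
  n_ticks <- round(segs$dur / dt)
  tibble(
    time = seq_len(sum(n_ticks)) * dt,
    step = rep(segs$label, n_ticks),
    iap_set = rep(segs$iap, n_ticks),
    hold_phase = rep(segs$phase, n_ticks)
  )
}

# Core fixed-step simulation engine shared by run_protocol() and
# run_closed_loop(): advances the subject along a schedule, records one log
# row per tick and executes the controller at multiples of cfg$interval.
.simulate_timeline <- function(schedule, params, cfg, vent, state,
                               dt, seed, noise, override = NULL,
                               header_extra = list()) {
  n <- nrow(schedule)
  rng <- if (noise) make_noise_streams(seed) else NULL
  win_ticks <- max(1L, ceiling(cfg$avg_window / dt))

  num_cols <- c(
    "time", "iap_set", "iap", "etco2", "spo2", "ori", "pip", "paco2",
    "pao2", "map_art", "cvp", "heart_rate", "rr", "fio2", "vt", "peep", "ti"
  )
  rec <- lapply(setNames(num_cols, num_cols), function(.) numeric(n))
  rec$step <- character(n)
  rec$hold <- logical(n)
  rec$hold_phase <- rep(NA_character_, n)
  rec$valid <- logical(n)
  rec$cmd <- logical(n)
  rec$override <- logical(n)

  cmd_time <- numeric(0)
  cmd_rr <- numeric(0)
  cmd_fio2 <- numeric(0)
  cmd_over <- logical(0)

  insuff <- insufflator_settings(0, iap_max = max(c(schedule$iap_set, 20)))
  for (k in seq_len(n)) {
    phase <- schedule$hold_phase[k]
    in_hold <- !is.na(phase)
    insuff$iap_setpoint <- schedule$iap_set[k]
    state <- tryCatch(
      advance_subject(state, params, vent, insuff, dt = dt, breath_hold = in_hold),
      insuvent_simulation_error = function(e) {
        abort(sprintf("[step %s] %s", schedule$step[k], conditionMessage(e)),
          class = "insuvent_simulation_error"
        )
      }
    )
    smp <- .observe_raw(state, params, vent, insuff,
      hold_phase = phase, noise_rng = rng
    )

    rec$time[k] <- state$time
    rec$step[k] <- schedule$step[k]
    rec$iap_set[k] <- schedule$iap_set[k]
    rec$iap[k] <- smp$iap
    rec$etco2[k] <- smp$etco2
    rec$spo2[k] <- smp$spo2
    rec$ori[k] <- smp$ori
    rec$pip[k] <- smp$pip
    rec$paco2[k] <- smp$paco2
    rec$pao2[k] <- smp$pao2
    rec$map_art[k] <- smp$map_art
    rec$cvp[k] <- smp$cvp
    rec$heart_rate[k] <- smp$heart_rate
    rec$hold[k] <- in_hold
    rec$hold_phase[k] <- phase
    rec$valid[k] <- TRUE
    rec$rr[k] <- vent$rr
    rec$fio2[k] <- vent$fio2
    rec$vt[k] <- vent$vt
    rec$peep[k] <- vent$peep
    rec$ti[k] <- vent$ti

    tm <- state$time
    if (abs(tm / cfg$interval - round(tm / cfg$interval)) < 1e-9) {
      idx <- max(1L, k - win_ticks + 1L):k
      win <- tibble(
        timestamp = rec$time[idx], etco2 = rec$etco2[idx],
        spo2 = rec$spo2[idx], ori = rec$ori[idx],
        hold = rec$hold[idx], valid = rec$valid[idx]
      )
      input <- condition_measurements(win, tm, cfg)
      if (!input$breath_hold && !input$stale) {
        new_vent <- control_cycle(input, vent, cfg)
        over <- FALSE
        if (!is.null(override)) {
          cand <- override(tm, new_vent)
          over <- !identical(
            cand[c("rr", "fio2", "vt", "peep", "ti")],
            new_vent[c("rr", "fio2", "vt", "peep", "ti")]
          )
          new_vent <- cand
        }
        vent <- new_vent
        rec$cmd[k] <- TRUE
        rec$override[k] <- over
        cmd_time <- c(cmd_time, tm)
        cmd_rr <- c(cmd_rr, vent$rr)
        cmd_fio2 <- c(cmd_fio2, vent$fio2)
        cmd_over <- c(cmd_over, over)
      }
    }
  }

  log <- as_tibble(rec[c(
    "time", "step", "iap_set", "iap", "etco2", "spo2", "ori", "pip",
    "paco2", "pao2", "map_art", "cvp", "heart_rate", "hold", "hold_phase",
    "valid", "rr", "fio2", "vt", "peep", "ti", "cmd", "override"
  )])
  header <- c(
    list(
      format = "insuvent run log v1",
      package_version = as.character(packageVersion("insuvent")),
      seed = seed, dt = dt, noise = noise,
      subject = unclass(params)[setdiff(names(params), "noise_sd")],
      noise_sd = as.list(params$noise_sd),
      controller = unclass(cfg),
      vent_initial = unclass(vent)[c("vt", "peep", "ti", "volume_guarantee")]
    ),
    header_extra
  )
  new_run_log(log, header,
    commands = tibble(
      time = cmd_time, rr = cmd_rr, fio2 = cmd_fio2, override = cmd_over
    )
  )
}

#' Run the full automated experiment protocol
#'
#' Simulates the complete timeline against the virtual subject: at each
#' step the insufflator setpoint is commanded and ramped, the subject is
#' advanced at the integration step `dt`, the closed-loop controller
#' executes at multiples of its interval (halting during breath holds), and
#' every record is labelled with its step. The subject starts from the
#' closed-form equilibrium for the initial settings at zero IAP.
#'
#' @param protocol An `insu_protocol`, e.g. [default_protocol()].
#' @param params A [subject_params()] record.
#' @param cfg A [controller_config()].
#' @param vent Initial [ventilator_settings()]; the tidal volume defaults
#'   to [tidal_volume_setting()] of the subject weight.
#' @param dt Integration step, s.
#' @param seed Integer seed for the per-channel noise substreams.
#' @param noise Logical; draw sensor noise.
#' @param hold_recovery Ventilated recovery time after each breath hold
#'   before the protocol proceeds, s.
#' @param override Optional manual-override hook, a
#'   `function(time, settings)` returning possibly modified settings;
#'   applied after each executed control cycle and logged with an override
#'   flag.
#' @return An `insu_run_log` tibble (one row per tick) carrying the full
#'   configuration snapshot as its header and the command trace as an
#'   attribute.
#' @export
run_protocol <- function(protocol = default_protocol(),
                         params = subject_params(),
                         cfg = controller_config(),
                         vent = NULL,
                         dt = 1,
                         seed = 1L,
                         noise = TRUE,
                         hold_recovery = 20,
                         override = NULL) {
  if (is.null(vent)) {
    vent <- ventilator_settings(vt = tidal_volume_setting(params$weight))
  }
  schedule <- .build_schedule(protocol, dt, hold_recovery)
  state <- initial_subject_state(params, vent, iap = 0)
  .simulate_timeline(
    schedule, params, cfg, vent, state, dt, seed, noise, override,
    header_extra = list(
      protocol = attr(protocol, "name"),
      n_steps = nrow(protocol),
      hold_recovery = hold_recovery
    )
  )
}

#' Free-running closed-loop simulation at constant insufflation pressure
#'
#' @param duration Simulated duration, s.
#' @param iap Constant insufflator setpoint, hPa.
#' @inheritParams run_protocol
#' @return An `insu_run_log` tibble.
#' @export
run_closed_loop <- function(duration = 1200,
                            iap = 0,
                            params = subject_params(),
                            cfg = controller_config(),
                            vent = NULL,
                            dt = 1,
                            seed = 1L,
                            noise = TRUE) {
  if (is.null(vent)) {
    vent <- ventilator_settings(vt = tidal_volume_setting(params$weight))
  }
  n <- round(duration / dt)
  schedule <- tibble(
    time = seq_len(n) * dt,
    step = "free_run",
    iap_set = iap,
    hold_phase = NA_character_
  )
  state <- initial_subject_state(params, vent, iap = 0)
  .simulate_timeline(
    schedule, params, cfg, vent, state, dt, seed, noise,
    header_extra = list(protocol = "free_run", n_steps = 1L, hold_recovery = 0)
  )
}

#' Advance the subject through a breath hold
#'
#' Ventilation ceases for the duration: alveolar ventilation is zero, the
#' lung is held at the end-expiratory (PEEP) or end-inspiratory
#' (PEEP + tidal inflation) volume per `phase`, arterial CO2 accumulates
#' from the ongoing load, and end-tidal samples are flagged invalid. Under
#' the lumped gas-kinetics model the two phases differ only in the held
#' airway pressure.
#'
#' @param state A [subject_state()].
#' @param params A [subject_params()] record.
#' @param vent A [ventilator_settings()] record.
#' @param insuff An [insufflator_settings()] record.
#' @param phase `"expiratory"` or `"inspiratory"`.
#' @param duration Hold duration, s.
#' @param dt Integration step, s.
#' @return The post-hold [subject_state()], with the per-tick samples in
#'   attribute `"trace"`.
#' @export
breath_hold <- function(state, params, vent, insuff,
                        phase = c("expiratory", "inspiratory"),
                        duration = 20, dt = 1) {
  phase <- match.arg(phase)
  if (duration <= 0) abort("`duration` must be positive.", class = "insuvent_validation_error")
  n <- round(duration / dt)
  trace <- vector("list", n)
  for (k in seq_len(n)) {
    state <- advance_subject(state, params, vent, insuff, dt = dt, breath_hold = TRUE)
    trace[[k]] <- observe_subject(state, params, vent, insuff, hold_phase = phase)
  }
  state$breath_hold_active <- FALSE
  attr(state, "trace") <- bind_rows(trace)
  state
}
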