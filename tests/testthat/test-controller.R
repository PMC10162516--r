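cfg <- controller_config()

test_that("conditioning averages valid samples over the trailing window", {
  s <- make_samples(etco2 = c(6.8, 7.0, 7.2, 7.0, 7.0), times = 1:5)
  inp <- condition_measurements(s, now = 5, cfg)
  expect_equal(inp$etco2_avg, 7.0)
  expect_false(inp$stale)
  # window is (now - avg_window, now]: the sample at t = 1 falls outside at now = 6
  inp2 <- condition_measurements(make_samples(etco2 = c(9, 7, 7, 7, 7, 7), times = 1:6), 6, cfg)
  expect_equal(inp2$etco2_avg, 7.0)
})

test_that("invalid and out-of-range samples are excluded; all-invalid is stale", {
  s <- make_samples(etco2 = c(7, 25, 7), valid = c(TRUE, TRUE, TRUE), times = 1:3)
  expect_equal(condition_measurements(s, 3, cfg)$etco2_avg, 7) # 25 kPa out of range
  s2 <- make_samples(valid = FALSE, times = 1:5)
  inp2 <- condition_measurements(s2, 5, cfg)
  expect_true(inp2$stale)
  expect_true(is.na(inp2$etco2_avg))
})

test_that("hold samples drop out of the end-tidal average but not SpO2", {
  s <- make_samples(
    etco2 = c(7, 9, 9, 7, 7), spo2 = c(98, 97, 97, 98, 98),
    hold = c(FALSE, TRUE, TRUE, FALSE, FALSE), times = 1:5
  )
  inp <- condition_measurements(s, 5, cfg)
  expect_equal(inp$etco2_avg, 7) # hold readings excluded
  expect_equal(inp$spo2_avg, mean(c(98, 97, 97, 98, 98)))
  expect_false(inp$breath_hold) # hold not active at `now`
  s_at_hold <- make_samples(hold = c(FALSE, FALSE, TRUE), times = 1:3)
  expect_true(condition_measurements(s_at_hold, 3, cfg)$breath_hold)
})

test_that("the CO2 branch steps the rate toward target and respects all clamps", {
  expect_equal(co2_branch(controller_input(etco2_avg = 7.5), 20, cfg), 21)
  expect_equal(co2_branch(controller_input(etco2_avg = 6.5), 20, cfg), 19)
  expect_equal(co2_branch(controller_input(etco2_avg = 7.1), 20, cfg), 20) # deadband
  expect_equal(co2_branch(controller_input(etco2_avg = 8.0), 37, cfg), 37) # hardware ceiling
  expect_equal(co2_branch(controller_input(etco2_avg = 5.0), 10, cfg), 10) # safety floor
  expect_equal(co2_branch(controller_input(etco2_avg = NA_real_), 20, cfg), 20)
  # the safety floor only binds above the hardware minimum
  lo <- controller_config(rr_min_safety = 4)
  expect_equal(co2_branch(controller_input(etco2_avg = 5.0), 5, lo), 4)
})

test_that("the O2 branch titrates FiO2 on the SpO2/ORI bands", {
  expect_equal(o2_branch(controller_input(spo2_avg = 97.5, ori_avg = 0.2), 40, cfg), 41)
  expect_equal(o2_branch(controller_input(spo2_avg = 100, ori_avg = 0.5), 40, cfg), 39)
  expect_equal(o2_branch(controller_input(spo2_avg = 100, ori_avg = 0.5), 21, cfg), 21) # room-air floor
  expect_equal(o2_branch(controller_input(spo2_avg = 96, ori_avg = 0.2), 100, cfg), 100) # ceiling
  # hypoxia protection dominates a high reserve-index reading
  expect_equal(o2_branch(controller_input(spo2_avg = 96, ori_avg = 0.6), 40, cfg), 41)
  # saturated with the reserve index inside its band: hold
  expect_equal(o2_branch(controller_input(spo2_avg = 99.5, ori_avg = 0.2), 40, cfg), 40)
  expect_equal(o2_branch(controller_input(spo2_avg = NA_real_, ori_avg = NA_real_), 40, cfg), 40)
})

test_that("a control cycle freezes on breath hold or stale input and fixed fields never move", {
  v <- ventilator_settings(rr = 20, fio2 = 40)
  inp_hold <- controller_input(etco2_avg = 9, spo2_avg = 97.5, breath_hold = TRUE)
  expect_identical(control_cycle(inp_hold, v, cfg), v)
  inp_stale <- controller_input(
    etco2_avg = NA_real_, spo2_avg = NA_real_,
    ori_avg = NA_real_, stale = TRUE
  )
  expect_identical(control_cycle(inp_stale, v, cfg), v)
  out <- control_cycle(controller_input(etco2_avg = 9, spo2_avg = 97.5, ori_avg = 0.2), v, cfg)
  expect_equal(out$rr, 21)
  expect_equal(out$fio2, 41)
  expect_identical(out[c("vt", "peep", "ti")], v[c("vt", "peep", "ti")])
})

test_that("sustained high etCO2 ramps the rate one step per cycle", {
  v <- ventilator_settings(rr = 20)
  for (i in 1:10) v <- control_cycle(controller_input(etco2_avg = 9), v, cfg)
  expect_equal(v$rr, 30) # 20 + 10 x 1
})

test_that("the decision table matches a brute-force oracle on all 27 regions", {
  # oracle written directly from the control rules: RR follows the etCO2
  # deadband alone; FiO2 rises inside the SpO2 band with ORI in band or on
  # hypoxia, falls on high ORI.
  oracle <- function(et, s, o, cfg) {
    drr <- if (et > cfg$etco2_target + cfg$etco2_deadband) {
      +1
    } else if (et < cfg$etco2_target - cfg$etco2_deadband) {
      -1
    } else {
      0
    }
    dfio2 <- if (s < cfg$spo2_min) {
      +1
    } else if (s >= cfg$spo2_band_lo && s <= cfg$spo2_band_hi &&
      o >= cfg$ori_lo && o <= cfg$ori_hi) {
      +1
    } else if (o > cfg$ori_hi) {
      -1
    } else {
      0
    }
    c(drr, dfio2)
  }
  grid <- expand.grid(
    et = c(6.5, 7.0, 7.5), # below / inside / above the deadband
    s = c(96, 97.5, 99.5), # hypoxic / in band / saturated
    o = c(0.0, 0.2, 0.7) # band edge / in band / above band
  )
  v0 <- ventilator_settings(rr = 20, fio2 = 40)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    out <- control_cycle(controller_input(g$et, g$s, g$o), v0, cfg)
    expect_equal(
      c(out$rr - v0$rr, out$fio2 - v0$fio2),
      oracle(g$et, g$s, g$o, cfg),
      info = sprintf("region et=%g spo2=%g ori=%g", g$et, g$s, g$o)
    )
  }
})

test_that("the branches are independent: each ignores the other's signals", {
  v0 <- ventilator_settings(rr = 20, fio2 = 40)
  set.seed(11)
  for (i in 1:200) {
    et <- runif(1, 5, 9)
    s1 <- runif(1, 90, 100)
    s2 <- runif(1, 90, 100)
    o1 <- runif(1, 0, 1)
    o2 <- runif(1, 0, 1)
    expect_equal(
      co2_branch(controller_input(et, s1, o1), v0$rr, cfg),
      co2_branch(controller_input(et, s2, o2), v0$rr, cfg)
    )
    et2 <- runif(1, 5, 9)
    expect_equal(
      o2_branch(controller_input(et, s1, o1), v0$fio2, cfg),
      o2_branch(controller_input(et2, s1, o1), v0$fio2, cfg)
    )
  }
})

test_that("clamps survive fuzzed input streams and steps never exceed one increment", {
  set.seed(99)
  v <- ventilator_settings(rr = 20, fio2 = 40)
  for (i in 1:500) {
    inp <- controller_input(
      etco2_avg = runif(1, 0, 15),
      spo2_avg = runif(1, 50, 100),
      ori_avg = runif(1, 0, 1),
      breath_hold = runif(1) < 0.1,
      stale = runif(1) < 0.1
    )
    new <- control_cycle(inp, v, cfg)
    expect_lte(abs(new$rr - v$rr), cfg$rr_step)
    expect_lte(abs(new$fio2 - v$fio2), cfg$fio2_step)
    expect_gte(new$rr, max(cfg$rr_min_hw, cfg$rr_min_safety))
    expect_lte(new$rr, cfg$rr_max_hw)
    expect_gte(new$fio2, 21)
    expect_lte(new$fio2, 100)
    v <- new
  }
})

test_that("configuration invariants are enforced", {
  expect_error(controller_config(rr_min_safety = 2), class = "insuvent_validation_error")
  expect_error(controller_config(spo2_band_lo = 99, spo2_band_hi = 98),
    class = "insuvent_validation_error"
  )
  expect_error(controller_config(ori_lo = 0.5, ori_hi = 0.4),
    class = "insuvent_validation_error"
  )
  expect_error(controller_config(interval = 0), class = "insuvent_validation_error")
})
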