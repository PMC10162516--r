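p <- subject_params()
v <- ventilator_settings()

test_that("alveolar ventilation is rate times volume above dead space", {
  pp <- subject_params(vd = 60)
  expect_equal(alveolar_ventilation(ventilator_settings(vt = 160, rr = 20), pp), 2000)
  expect_equal(alveolar_ventilation(v, p, breath_hold = TRUE), 0)
  expect_error(
    alveolar_ventilation(ventilator_settings(vt = 50), subject_params(vd = 60)),
    class = "insuvent_simulation_error"
  )
})

test_that("CO2 load is metabolic production plus linear peritoneal uptake", {
  expect_equal(co2_load(0, p), p$vco2_met)
  pp <- subject_params(k_perit = 2)
  expect_equal(co2_load(10, pp), pp$vco2_met + 20)
  # uptake component is linear in IAP
  expect_equal(co2_load(16, p) - p$vco2_met, 2 * (co2_load(8, p) - p$vco2_met))
  expect_true(all(diff(co2_load(seq(0, 20, 2), p)) >= 0))
})

test_that("the closed-form equilibrium is a fixed point of advance()", {
  ins <- insufflator_settings(10)
  st <- initial_subject_state(p, v, iap = 10)
  st2 <- st
  for (i in 1:300) st2 <- advance_subject(st2, p, v, ins, dt = 1)
  expect_equal(st2$paco2, st$paco2, tolerance = 1e-12)
  expect_equal(st2$pao2, st$pao2, tolerance = 1e-12)
  # and the fixed point equals the analytic steady state load * pb_dry / VA
  va <- alveolar_ventilation(v, p)
  expect_equal(st$paco2, co2_load(10, p) * p$pb_dry / va)
})

test_that("trajectories converge to the analytic steady state", {
  ins <- insufflator_settings(10)
  st <- initial_subject_state(p, v, iap = 0) # perturbed: tissue charged for IAP 0
  target <- co2_load(10, p) * p$pb_dry / alveolar_ventilation(v, p)
  for (i in 1:8000) st <- advance_subject(st, p, v, ins, dt = 5)
  expect_equal(st$paco2, target, tolerance = 0.01)
})

test_that("steady-state expired CO2 equals metabolic production plus peritoneal uptake", {
  for (iap in c(0, 10, 20)) {
    ins <- insufflator_settings(iap)
    st <- initial_subject_state(p, v, iap = iap)
    for (i in 1:120) st <- advance_subject(st, p, v, ins, dt = 1)
    expired <- alveolar_ventilation(v, p) * st$paco2 / p$pb_dry
    expect_equal(expired, co2_load(iap, p), tolerance = 0.01)
  }
})

test_that("PaCO2 rises during a breath hold and equilibrium holds otherwise", {
  ins <- insufflator_settings(0)
  st <- initial_subject_state(p, v)
  held <- st
  for (i in 1:60) {
    old <- held$paco2
    held <- advance_subject(held, p, v, ins, dt = 1, breath_hold = TRUE)
    expect_gt(held$paco2, old)
  }
})

test_that("steady-state PaCO2 strictly decreases with respiratory rate", {
  paco2_ss <- vapply(10:30, function(rr) {
    initial_subject_state(p, ventilator_settings(rr = rr))$paco2
  }, numeric(1))
  expect_true(all(diff(paco2_ss) < 0))
})

test_that("PIP strictly increases with IAP at fixed tidal volume and PEEP", {
  ins <- insufflator_settings(0)
  pips <- vapply(seq(0, 20, 2), function(iap) {
    st <- initial_subject_state(p, v, iap = iap)
    observe_subject(st, p, v, ins)$pip
  }, numeric(1))
  expect_true(all(diff(pips) > 0))
  # undamped compliance at IAP 0: PIP = PEEP + Vt / Crs0
  expect_equal(pips[1], v$peep + v$vt / p$crs0)
})

test_that("SpO2 is non-decreasing in FiO2", {
  spo2 <- vapply(seq(21, 100, 5), function(f) {
    st <- initial_subject_state(p, ventilator_settings(fio2 = f))
    observe_subject(st, p, ventilator_settings(fio2 = f), insufflator_settings(0))$spo2
  }, numeric(1))
  expect_true(all(diff(spo2) >= 0))
})

test_that("the reserve index maps PaO2 linearly between its endpoints", {
  ins <- insufflator_settings(0)
  at <- function(pao2) {
    st <- subject_state(7, 9, pao2)
    observe_subject(st, p, v, ins)$ori
  }
  expect_equal(at(p$pao2_ori_lo), 0)
  expect_equal(at(p$pao2_ori_hi), 1)
  expect_equal(at(150), 0.5)
  expect_equal(at(50), 0) # clamped below
  expect_equal(at(400), 1) # clamped above
})

test_that("observation flags breath holds and reads held airway pressures", {
  ins <- insufflator_settings(0)
  st <- initial_subject_state(p, v)
  s_exp <- observe_subject(st, p, v, ins, hold_phase = "expiratory")
  s_insp <- observe_subject(st, p, v, ins, hold_phase = "inspiratory")
  s_vent <- observe_subject(st, p, v, ins)
  expect_true(s_exp$hold && s_insp$hold && !s_vent$hold)
  expect_equal(s_exp$pip, v$peep)
  expect_equal(s_insp$pip, s_vent$pip)
})

test_that("end-tidal CO2 is arterial tension minus the gradient, floored at zero", {
  ins <- insufflator_settings(0)
  st <- subject_state(7.5, 9.5, 130)
  expect_equal(observe_subject(st, p, v, ins)$etco2, 7.5 - p$et_gradient)
  low <- subject_state(0.2, 1, 130)
  expect_equal(observe_subject(low, p, v, ins)$etco2, 0)
})

test_that("noise substreams are reproducible and mutually independent", {
  ins <- insufflator_settings(0)
  st <- initial_subject_state(p, v)
  r1 <- make_noise_streams(42)
  r2 <- make_noise_streams(42)
  a <- observe_subject(st, p, v, ins, noise_rng = r1)
  b <- observe_subject(st, p, v, ins, noise_rng = r2)
  expect_identical(a, b)
  # disabling one channel leaves the draws of another untouched
  p_no_et <- subject_params(noise_sd = c(
    etco2 = 0, spo2 = 0.1, ori = 0.005, pip = 0.2,
    map_art = 1.5, cvp = 0.5, heart_rate = 1.0
  ))
  r3 <- make_noise_streams(42)
  c_ <- observe_subject(st, p_no_et, v, ins, noise_rng = r3)
  expect_identical(c_$spo2, a$spo2)
  expect_identical(c_$pip, a$pip)
})

test_that("halving the integration step changes trajectories by less than 0.1%", {
  l1 <- run_protocol(seed = 1, noise = FALSE, dt = 1)
  l2 <- run_protocol(seed = 1, noise = FALSE, dt = 0.5)
  m <- match(l1$time, l2$time)
  expect_false(anyNA(m))
  expect_lt(max(abs(l1$paco2 - l2$paco2[m]) / l1$paco2), 0.001)
  expect_lt(max(abs(l1$pao2 - l2$pao2[m]) / l1$pao2), 0.001)
})

test_that("degenerate parameters are rejected", {
  expect_error(subject_params(weight = -1), class = "insuvent_validation_error")
  expect_error(subject_params(shunt = 1), class = "insuvent_validation_error")
  expect_error(subject_params(pao2_ori_lo = 300), class = "insuvent_validation_error")
  expect_error(subject_state(-1, 9, 100), class = "insuvent_validation_error")
  expect_error(
    advance_subject(initial_subject_state(p, v), p, v, insufflator_settings(0), dt = 0),
    class = "insuvent_validation_error"
  )
})
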