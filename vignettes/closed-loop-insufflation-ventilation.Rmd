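---
title: "Methods: the virtual subject, the closed-loop controller, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual subject, the closed-loop controller, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insuvent)
```

`insuvent` replaces the animal, the ventilator and the insufflator of an
automated insufflation–ventilation experiment with code, so the control
logic and the protocol engine can be exercised, fuzzed and regression-tested
at desk scale. This vignette is the package's own account of the model, the
parameters that matter, the numerical choices, and — importantly — what
passing tests do and do not say about real animals.

## The virtual subject

### CO₂: two pools, two time scales

A ventilated subject shows two distinct CO₂ time scales. End-tidal CO₂
responds to a rate change or a breath hold within tens of seconds, because
the arterial/alveolar compartment is small; yet the whole body charges and
discharges CO₂ over tens of minutes, because tissue stores are enormous. A
single well-mixed pool cannot show both: its breath-hold rise rate times
its washout time constant is pinned to `PaCO₂ × t_hold` regardless of the
capacitance chosen, so one either gets an absurd 2–4 kPa rise per 20 s
hold or a controller that needs ten minutes to recover. We therefore model
two pools:

* a **fast pool** (arterial + alveolar, stiffness `k_store` = 0.025
  kPa/mL, i.e. a 40 mL/kPa capacitance) that receives peritoneal uptake
  `k_perit · IAP` and is washed out by alveolar ventilation
  `V̇A · PaCO₂ / Pb'`;
* a **tissue store** (stiffness `k_tissue` = 5·10⁻⁴ kPa/mL, a 2 L/kPa
  capacitance) fed by metabolic production and exchanging with the fast
  pool at conductance `D` = 45 mL·min⁻¹·kPa⁻¹.

During a 20 s hold the fast pool rises only ~0.7 kPa (its inflow is the
~100 mL/min load), and after the hold the excess washes out with the fast
pool's ~40 s time constant, because the tissue store never charged. Both
behaviors are what the bedside shows, and both are what the ±1 bpm / 40 s
controller was designed against. At steady state the expired CO₂ rate
equals `V̇CO₂ + k_perit·IAP` exactly — the conservation property the
package tests to 1%, and the reason holding etCO₂ constant turns expired
CO₂ volume into a peritoneal-uptake readout.

### Oxygen

PaO₂ is a single pool relaxing (τ = 45 s) toward
`(1 − shunt) · (FiO₂/100 · Pb' − PaCO₂/0.8)` in mmHg — the alveolar gas
equation with respiratory quotient 0.8 reduced by a 7% venous admixture.
During apnea the target switches to a fixed 85 mmHg: a 20 s hold in a
preoxygenated subject barely dents saturation, which is precisely the
oxygen buffer the FiO₂ branch maintains. SpO₂ is the Severinghaus curve;
the oxygen reserve index is modelled as a clamped linear map of PaO₂
between 100 and 200 mmHg — the simplest monotone surrogate for an index of
the hyperoxic buffer.

### Mechanics and descriptive signals

Respiratory-system compliance falls with insufflation as
`Crs = Crs0 / (1 + k_crs·IAP)` (Crs0 = 20 mL/hPa, k_crs = 0.05 /hPa), so
PIP = PEEP + Vt/Crs doubles its elastic component across the 0–20 hPa
staircase (13 → 21 hPa). Arterial and venous pressures and heart rate are
emitted as *descriptive* signals only — plausible trends for plotting, not
mechanistic outputs — and nothing downstream consumes them.

## Parameters, units, defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `weight` | kg | 21.5 | pilot-scale subject; sets Vt = 160 mL at 7.5 mL/kg |
| `vco2_met` | mL/min | 90 | ~4 mL/kg/min, anesthetized juvenile pig |
| `vd` | mL | 100 | anatomical + apparatus dead space |
| `k_perit` | mL/min/hPa | 1.0 | peritoneal uptake slope; +20 mL/min at 20 hPa |
| `k_store` | kPa/mL | 0.025 | fast-pool stiffness; ~0.7 kPa rise per 20 s hold |
| `k_tissue` | kPa/mL | 5e-4 | tissue store ~50× the fast pool |
| `d_tissue` | mL/min/kPa | 45 | tissue–blood exchange; fast-pool τ ≈ 40 s |
| `pb_dry` | kPa | 95 | barometric − water vapour |
| `crs0`, `k_crs` | mL/hPa, /hPa | 20, 0.05 | compliance and its loss to IAP |
| `shunt` | – | 0.07 | venous admixture |
| `o2_tau`, `pao2_hold` | s, mmHg | 45, 85 | O₂ pool speed; apneic tension |
| `et_gradient` | kPa | 0.5 | PaCO₂ − etCO₂ offset |
| `iap_ramp_rate` | hPa/s | 5 | insufflators are flow-limited; no step jumps |

Controller defaults (7.0 kPa target, 4–37 bpm range with a 10 bpm safety
floor, 1 bpm and 1% steps, 97–98% SpO₂ band, 97% minimum, 0.0–0.4 ORI
band, 40 s interval, 5 s averaging window) are the platform's pilot
configuration. Two controller values are package choices where the
platform states none:

* **etCO₂ deadband ±0.2 kPa.** A pure target with ±1 bpm action
  limit-cycles between adjacent rate settings, whose equilibria sit
  ~0.35 kPa apart; a deadband of at least half that spacing lets the rate
  rest. Configurable.
* **Contradictory O₂ signals.** SpO₂ < 97% with ORI > 0.4 raises FiO₂ —
  hypoxia protection dominates. SpO₂ at 99–100% with ORI inside 0.0–0.4
  holds FiO₂, because the increase rule is conditioned on the 97–98%
  band. Both are configuration, not inference about authorial intent.

Calibration was done once, before the behavioral tests were frozen, by
sweeping `k_store` and `d_tissue` over a coarse grid and requiring the
design behavior: every staircase step settles inside its 3-minute
stabilization window and hold-onset etCO₂ stays within ±0.3 kPa of
target. With these defaults an IAP step from 0 to 20 hPa at *fixed*
ventilation raises steady-state etCO₂ by ≈1.5 kPa; under closed loop the
controller absorbs it with ~6 bpm.

## The protocol engine

Steps are timed from stabilization start; the two 20 s holds *extend*
each step beyond the 180 s stabilization (holds happen after it), and each
hold is followed by a 20 s ventilated recovery — the scanner repositioning
time — so the default step lasts 260 s and the full staircase ≈56
simulated minutes. Breath holds freeze actuation three ways, each tested
separately: alveolar ventilation is zero in the subject, the end-tidal
channel is flagged invalid at the source, and the controller skips any
cycle whose current sample lies in a hold. Expiratory and inspiratory
holds share identical gas kinetics under this lumped model and differ only
in the held airway pressure (PEEP versus PEEP + Vt/Crs); a test asserts
that equality rather than hiding it.

## Numerical choices

* **Integration**: fixed-step explicit fourth-order Runge–Kutta for the
  CO₂ pools at dt = 1 s (configurable), and the exact exponential update
  for the linear PaO₂ relaxation. The fastest time constant is ~40 s, so
  halving dt moves trajectories by < 0.1% (tested; observed ~2·10⁻⁴).
* **Quantization**: tidal volume rounds to the nearest 10 mL with ties
  toward the *lower* volume (the lung-protective direction); that rule is
  what maps 21.5 kg × 7.5 mL/kg = 161.25 onto the 160 mL setting.
* **Units**: all pressures are stored in hPa. Ventilation pressures are
  *labelled* cmH₂O 1:1 on plot axes (device display convention); the exact
  factors (1 hPa = 0.750062 mmHg = 1.019716 cmH₂O) are applied wherever a
  real conversion is meant, e.g. the mmHg right axis of the pressure
  panel.
* **Determinism**: one run seed feeds per-channel noise substreams, so
  disabling one channel's noise cannot perturb another's draws, and a
  noise-free run is bit-reproducible. Logs re-read from CSV are bit-exact
  (written with shortest-round-trip formatting, parsed with strtod) and a
  replay of a run's own log reproduces its command trace identically.
* **Degenerate inputs**: tidal volume at or below dead space raises a
  simulation-infeasible error carrying the protocol step label; a clock
  regression in the log is a logging error; staleness of conditioned
  measurements is signalled, never thrown, and freezes actuation.

## What the generator does and does not emulate

The virtual subject reproduces the *qualitative* physiology the control
loop needs: two-time-scale CO₂ kinetics obeying the steady-state mass
balance, monotone PaCO₂–rate and PIP–IAP relations, a hyperoxic buffer
with a saturating dissociation curve, finite insufflator slew, and
Gaussian sensor noise. It does not emulate intra-breath waveforms,
ventilation–perfusion heterogeneity, hemodynamic feedback on gas exchange,
measurement dropouts, capnograph response times, or inter-animal
variability; its constants are effective values chosen for behavior, not
estimates fitted to any animal. Passing tests therefore certify the
*controller and protocol logic* — limits, step sizes, timing, hold
semantics, settling under the modelled plant — and say nothing about
performance on a real pig beyond consistency with the platform's reported
behavior.

## Problem sizes

The default staircase run is 3,380 one-second ticks (≈56 simulated
minutes, ~1 s wall time); the constant-IAP regulation run is 20 simulated
minutes; convergence checks integrate up to 40,000 simulated seconds at
dt = 5 s; the controller fuzz suites use 500–1,000 random inputs under
fixed seeds. These sizes were chosen so the full suite re-runs in well
under a minute of compute while still crossing every time scale in the
model.

## Known limitations

* The ORI surrogate is linear in PaO₂; real ORI saturates nonlinearly and
  is device-specific.
* The apneic PaO₂ target is a constant, so very long holds would be overly
  forgiving; the protocol's 20 s holds stay in the regime the constant was
  chosen for.
* Compliance loss is memoryless, so up-leg and down-leg plateaus at equal
  IAP read identical PIP; real lungs show hysteresis after recruitment
  changes.
* The controller is the platform's volume-guarantee variant; a
  pressure-control branch would require a different plant readout and is
  out of scope.
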