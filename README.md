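# insuvent

Laparoscopic surgery requires insufflating the abdomen with pressurized
CO₂. The resulting pneumoperitoneum competes with the lungs for space,
stiffens the respiratory system, and adds absorbed CO₂ to the metabolic
load — so experiments that vary intra-abdominal pressure (IAP) while
measuring its mechanical effects are confounded by drifting blood gases
unless ventilation is actively re-titrated. `insuvent` is an in-silico
testbed for exactly that experimental platform: a closed-loop ventilation
controller that holds end-tidal CO₂ (etCO₂) and oxygenation constant while
an automated protocol engine steps IAP through a staircase, all run against
a lumped-parameter virtual pig instead of an animal. It is aimed at people
developing or stress-testing physiological closed-loop control logic and
automated experiment protocols before any hardware or animal work.

## The model and controller

**Virtual subject.** CO₂ kinetics use two well-mixed pools. The fast
arterial/alveolar pool (tension `PaCO₂`, stiffness `k_store` in kPa/mL)
receives peritoneal uptake `k_perit · IAP` and exchanges with a large
tissue store (tension `Pt`, stiffness `k_tissue`) at conductance `D`;
metabolic production `V̇CO₂` enters the tissue side:

    dPaCO₂/dt = k_store · ( D·(Pt − PaCO₂) + k_perit·IAP − V̇A·PaCO₂/Pb' )
    dPt/dt    = k_tissue · ( V̇CO₂ − D·(Pt − PaCO₂) )

with alveolar ventilation `V̇A = RR·(Vt − Vd)` (zero during breath holds)
and `Pb'` the dry barometric pressure. At steady state the expired CO₂
rate equals `V̇CO₂ + k_perit·IAP` exactly — the mass balance that makes
expired CO₂ volume a readout of peritoneal uptake once etCO₂ is held
constant. PaO₂ relaxes toward an alveolar-gas/shunt target set by FiO₂ and
PaCO₂; SpO₂ follows the Severinghaus dissociation curve, and the oxygen
reserve index (ORI) is a clamped linear map of PaO₂. Respiratory-system
compliance falls with IAP as `Crs = Crs0 / (1 + k_crs·IAP)`, so at fixed
tidal volume and PEEP the peak inspiratory pressure (PIP) climbs directly
with insufflation pressure.

**Controller.** Every 40 s the most recent 5 s of valid measurements are
averaged and two independent branches act: respiratory rate moves 1 bpm
toward the 7.0 kPa etCO₂ target when the average leaves a ±0.2 kPa
deadband (hardware range 4–37 bpm, active safety floor 10 bpm), and FiO₂
moves 1% up when SpO₂ sits in 97–98% with ORI in 0.0–0.4 (or whenever
SpO₂ < 97%), 1% down when ORI exceeds 0.4. Actuation halts during breath
holds. Tidal volume (volume guarantee, 7.5 mL/kg), PEEP (5 hPa) and
inspiratory time (0.8 s) are never touched.

**Protocol engine.** The default experiment steps IAP through
0, 5, 8, 10, 12, 14, 16, 18, 20, 16, 10, 5, 0 hPa with a 3-minute
stabilization per step followed by an expiratory and an inspiratory 20 s
breath hold (the CT acquisition pauses), each with a 20 s ventilated
recovery. Runs are logged tick-by-tick on a single monotone clock and can
be replayed through the controller from CSV.

## Worked example

```r
library(insuvent)

log <- run_protocol(seed = 1)   # default staircase, sensor noise on
glance(log)
#> # A tibble: 1 × 10
#>   protocol      duration n_records n_steps n_commands max_iap_set min_spo2 max_ori final_rr final_fio2
#> 1 iap_staircase     3380      3380      13         70          20     97.9   0.379       20         30

step_summary(log)
#> # A tibble: 13 × 8
#>    step_label   iap settling_time settled etco2_at_hold pip_at_hold rr_at_hold fio2_at_hold
#>  1 s01_iap00      0           137 TRUE             6.79        13.1         16           30
#>  2 s02_iap05      5            26 TRUE             7.04        15.1         17           30
#>  3 s03_iap08      8            15 TRUE             7.00        16.3         19           30
#>  4 s04_iap10     10            23 TRUE             6.89        17.1         20           30
#>  ...
#>  9 s09_iap20     20           116 TRUE             6.84        21.1         25           30
#>  ...
#> 13 s13_iap00      0           175 TRUE             6.80        13.0         20           30

autoplot(log)                   # four-panel time series, holds shaded grey
```

Each row is one staircase plateau: `settling_time` is the time for etCO₂
to re-enter ±0.3 kPa of the 7.0 kPa target after the IAP step and stay
there until the first breath hold — every step settles inside the 180 s
stabilization window. `etco2_at_hold` shows the controller holding
permissive hypercapnia at the hold onset while `rr_at_hold` absorbs the
changing CO₂ load (16 → 25 bpm up the staircase). `pip_at_hold` rising
from 13 to 21 hPa at fixed tidal volume and PEEP is the compliance lost to
the pneumoperitoneum — the platform's primary interaction readout.

The same machinery works piecewise:

```r
convert_pressure(5, "hPa", "mmHg")   # 3.75031  (PEEP dual-axis label: 3.75)
tidal_volume_setting(21.5)           # 160 (mL, 7.5 mL/kg on the 10 mL grid)

cl <- run_closed_loop(duration = 1200, iap = 10, noise = FALSE)
mean(cl$etco2[cl$time > 1140])       # 6.956 -> 7.0 kPa held at constant IAP

write_run_log(log, "run1.csv")
replay("run1.csv")                   # identical command trace, from CSV
```

A thin command-line wrapper is installed at
`system.file("cli", "insuvent", package = "insuvent")` with `simulate`,
`run-protocol`, `replay` and `report` subcommands.

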