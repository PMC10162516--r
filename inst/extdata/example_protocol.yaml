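# A shortened two-plateau protocol: one control plateau at 0 hPa and one
# insufflated plateau at 12 hPa, each with a single expiratory hold.
name: two_plateau_demo
steps:
  - iap: 0
    stabilization: 120
    holds:
      - phase: expiratory
        duration: 20
  - iap: 12
    stabilization: 180
    holds:
      - phase: expiratory
        duration: 20
  - iap: 0
    stabilization: 120
    holds: []
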