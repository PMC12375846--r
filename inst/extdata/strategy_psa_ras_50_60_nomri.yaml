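name: psa_ras_50_60_nomri
primary_test: psa
start_age: 50.0
stop_age: 60.0
risk_bands:
  upper:
  - 1.5
  - 3.0
  - .inf
  interval_years:
  - 5.0
  - 2.0
  - 2.0
workup_threshold: 3.0
mri_triage: no
biopsy_type_on_workup: systematic
dre_interval: 1.0
recall_interval: 5.0
participation:
  first_screen: 0.75
  rescreen: 0.95
  biopsy: 0.65
symptomatic_workup: systematic
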