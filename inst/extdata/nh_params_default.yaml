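onset_hazard_params:
  shape: 1.8
  scale: 95.0
grade_mixture_params:
  int_gs7: -0.3
  int_gsgt7: -0.7
  age_slope: 0.03
  severity_gt7: 1.5
psa_baseline_level: 0.8
psa_pre_onset_slope: 0.02
psa_post_onset_slope_by_grade:
  gs_lt7: 0.12
  gs_7: 0.18
  gs_gt7: 0.25
psa_intercept_sd: 0.55
psa_slope_sd: 0.005
noise_sd: 0.3
progression_rate_params:
  t2_rate:
    gs_lt7: 0.07
    gs_7: 0.11
    gs_gt7: 0.18
  t3_rate:
    gs_lt7: 0.06
    gs_7: 0.1
    gs_gt7: 0.16
  met_rate:
    gs_lt7: 0.005
    gs_7: 0.012
    gs_gt7: 0.035
clinical_dx_params:
  rate_per_ngml: 0.012
  met_multiplier: 25.0
  age_attn_start: 75.0
  age_attn_rate: 0.35
survival_params:
  t_category:
  - 1
  - 2
  - 3
  - 1
  - 2
  - 3
  - 1
  - 2
  - 3
  - 1
  - 2
  - 3
  - 1
  - 2
  - 3
  - 1
  - 2
  - 3
  metastasis:
  - no
  - no
  - no
  - yes
  - yes
  - yes
  - no
  - no
  - no
  - yes
  - yes
  - yes
  - no
  - no
  - no
  - yes
  - yes
  - yes
  grade_category:
  - gs_7
  - gs_7
  - gs_7
  - gs_7
  - gs_7
  - gs_7
  - gs_gt7
  - gs_gt7
  - gs_gt7
  - gs_gt7
  - gs_gt7
  - gs_gt7
  - gs_lt7
  - gs_lt7
  - gs_lt7
  - gs_lt7
  - gs_lt7
  - gs_lt7
  cure_fraction:
  - 0.78
  - 0.7254
  - 0.6396
  - 0.05
  - 0.05
  - 0.05
  - 0.6
  - 0.558
  - 0.492
  - 0.02
  - 0.02
  - 0.02
  - 0.905
  - 0.84165
  - 0.7421
  - 0.08
  - 0.08
  - 0.08
  excess_rate:
  - 0.08
  - 0.112
  - 0.16
  - 0.25
  - 0.25
  - 0.25
  - 0.12
  - 0.168
  - 0.24
  - 0.3
  - 0.3
  - 0.3
  - 0.05
  - 0.07
  - 0.1
  - 0.2
  - 0.2
  - 0.2
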