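# prostascreen

A person-level microsimulation for evaluating the cost-effectiveness of
prostate-cancer screening policies from a statutory-health-insurance
perspective, built around the German policy question: keep annual digital
rectal examination (DRE), adopt PSA-based risk-adaptive screening
(PSA-RAS) with risk-dependent rescreen intervals, and/or triage biopsy
decisions with MRI?

The package contains, as tested code:

- a **natural-history model**: Weibull preclinical onset, age-linked
  Gleason-grade mixture, piecewise log-linear PSA growth with
  person-level random effects ($\log \mathrm{PSA}$ accelerates at onset by a
  grade-specific increment), exponential stage-progression clocks
  (3 T-levels × metastasis × 3 grades = 18 states), a PSA-proportional
  clinical-presentation hazard inverted in closed form, and per-state
  cure-fraction survival $S(t) = c + (1-c)e^{-rt}$;
- a **screening engine** for declarative strategies (no screening, annual
  DRE 45–75, PSA-RAS 45/50 → 60/70 ± MRI triage; thresholds 1.5/3 ng/mL,
  intervals 5/2 years) with participation, test characteristics, biopsy
  cascades, active surveillance, and the **stage-shift** survival benefit:
  screen-detected cancers get the survival of their earlier stage with the
  clock starting at the end of the lead time;
- exact per-person **overdiagnosis and lead time** via a counterfactual
  unscreened twin simulated under common random numbers;
- an **economics layer**: per-event and per-phase costs (2023 €, discounted
  3%/yr from age 45) and QALYs under a multiplicative
  background × health-state utility model;
- **cost-effectiveness machinery**: per-100,000 outcome tables, efficiency
  frontiers with strict and extended dominance and pairwise ICERs,
  cost-effectiveness acceptability curves (CEAC);
- **calibration** of onset and grade-mixture parameters to registry-style
  incidence/grade targets by Poisson + multinomial deviance under
  background DRE screening (Nelder–Mead with restarts, common random
  numbers), with mortality validation;
- **deterministic and probabilistic sensitivity analyses**; and
- a **synthetic-data module** that generates the life table and
  registry-style targets, so everything runs self-contained.

See `vignettes/model-and-methods.Rmd` for the full model description and
the reasoning behind the defaults.

## Worked example

```r
library(prostascreen)

cfg <- run_config(n_persons = 20000, master_seed = 1,
                  strategies = c("no_screening", "psa_ras_50_60_nomri",
                                 "psa_ras_50_70_mri", "dre_45_75"))
run <- run_strategies(cfg)
out <- run$outcomes
out[, c("strategy", "n_biopsies_screen", "n_dx_screen", "n_overdiagnosed",
        "n_pca_deaths", "qaly_disc", "cost_disc_meur")]
#>             strategy n_biopsies_screen n_dx_screen n_overdiagnosed n_pca_deaths qaly_disc cost_disc_meur
#>         no_screening                 0           0               0         4300   1826794       107.5794
#>  psa_ras_50_60_nomri             18235        1955             145         4220   1827125       116.0806
#>    psa_ras_50_70_mri             13460        3745             515         4100   1827365       147.8477
#>            dre_45_75            106250       10295            3225         3445   1829623       186.2447
```

All quantities are per 100,000 men followed from age 45 (costs in
millions of 2023 €, discounted at 3%/yr). Reading the table: annual DRE
screens hardest — it detects the most cancers and averts the most
prostate-cancer deaths, but at the price of about 106,000
screen-initiated biopsies and 3,225 overdiagnosed cancers per 100,000
men, and the highest cost. PSA-RAS (50–60) without MRI buys a similar
order of screening benefit with ~6× fewer screen-initiated biopsies;
adding MRI triage and extending to age 70 detects more cancers with
fewer biopsies per detection and less overdiagnosis.

```r
efficiency_frontier(out)$efficient
#>             strategy  effect     cost       icer
#>         no_screening 1826794 107.5794         NA
#>  psa_ras_50_60_nomri 1827125 116.0806 0.02562733
#>            dre_45_75 1829623 186.2447 0.02808700
```

The frontier is anchored at the least costly strategy; `icer` is in
millions of € per QALY between adjacent efficient strategies (0.0256 ≈
25,600 €/QALY). Strategies not listed are dominated (strictly or by
extended dominance). These numbers come from the shipped synthetic
parameterization at n = 20,000 — they illustrate the machinery, not a
German estimate.

Scenario and probabilistic analyses:

```r
dsa <- run_dsa(cfg, scenario_presets()[c("base", "scenario1_mri_120")])
psa <- run_probabilistic(cfg, n_iter = 100, cohort_n = 50000, seed = 1)
head(psa$ceac)   # P(cost-effective) per strategy across WTP thresholds
```

A command-line entry point wraps the same pipeline:

```sh
Rscript scripts/run_compare.R --n 100000 --seed 1 --out results \
    --scenario scenario1_mri_120
```

writing `outcomes.csv` (the per-100k table), `frontier.json` and a
reproducibility manifest.

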