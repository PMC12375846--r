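---
title: "Model and methods: natural history, screening strategies, and the economic layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostascreen)
```

`prostascreen` is a person-level microsimulation for evaluating the
cost-effectiveness of prostate-cancer screening policies in a German-style
statutory-health-insurance setting. It compares a no-screening baseline,
annual digital rectal examination (DRE) at ages 45–75, and eight PSA-based
risk-adaptive strategies (start 45 or 50, stop 60 or 70, with or without
MRI triage before biopsy). This vignette documents the model's structure,
its assumptions, the parameters that matter, and the choices made where
the design was genuinely open.

## The natural-history model

Each man is simulated from age 35 to death through six coupled
components.

**Other-cause mortality.** Drawn from an all-cause life table
(piecewise-constant annual hazards, inverted in closed form). The
shipped synthetic life table is Gompertz–Makeham,
$\mu(x) = A + B e^{\theta x}$ with $A = 8\times10^{-4}$,
$B = 3\times10^{-5}$, $\theta = 0.092$, giving a remaining life
expectancy at 45 of about 35 years — a contemporary German male cohort.
Any CSV life table with columns `age, mortality_rate` can be substituted.

**Preclinical onset.** A Weibull hazard in years since age 35 (default
shape 1.8, scale 95), giving a lifetime preclinical onset probability of
roughly 45% — most of it never destined to surface clinically.

**Grade.** Fixed at onset (no grade migration), drawn from an age-linked
three-category mixture (Gleason <7 / =7 / >7) parameterized as a
multinomial logit whose intercepts and a shared age slope shift mass
toward higher grades at older onset ages.

**PSA growth.** Log-PSA is piecewise linear in age: a person-specific
intercept (population median 0.8 ng/mL at 35, log-scale SD 0.55) and
slope (0.02/yr, SD 0.005) before onset, accelerating at onset by a
grade-specific increment to 0.12/0.18/0.25 per year. Continuity at onset
is structural. Measurement noise (SD 0.30 on the log scale) is applied
per test, not to the latent trajectory. These values put roughly 10% of
men over the 3 ng/mL work-up threshold at age 60, the order observed in
European screening cohorts.

**Stage progression and clinical presentation.** Local extent progresses
T1→T2→T3 by per-grade exponential clocks; an independent exponential
clock governs metastatic spread. Clinical diagnosis occurs with hazard
proportional to the latent (noise-free) PSA level, multiplied 25-fold
once metastatic, and attenuated exponentially (0.35/yr) beyond age 75 to
reproduce the decline of registry incidence in the very old — a
diagnostic-intensity effect, not a biological one. Because the hazard is
piecewise $C e^{K u}$ in time since onset, the diagnosis time inverts
analytically; the whole cohort simulates without time-stepping, which is
what makes 100,000-person calibration evaluations affordable. Whether
presentation should also depend directly on T stage is not identified by
the calibration targets; we use PSA plus the metastasis multiplier only.

**Survival after diagnosis.** Each of the 18 states (3 T levels × 2
metastasis states × 3 grades) carries a cure-fraction survival curve
$S(t) = c + (1-c)e^{-rt}$. Cure fractions fall and excess rates rise
with stage; the localized grade-group-1 curve ($c = 0.905$, $r = 0.05$)
evaluates to 0.95 at 15 years, the anchor the model is built around —
low-grade disease is indolent but not harmless. The defaults were chosen
so that, without screening, ~12% of men are diagnosed in their lifetime,
~20% of diagnoses are metastatic, and ~4% die of the disease, with
incidence peaking at ages 70–74.

**The stage-shift mechanism.** A screen-detected cancer is assigned the
survival curve of its (earlier) stage at detection, but the survival
clock starts at the *counterfactual clinical diagnosis age* — the end of
the lead time — so early detection is never credited with the lead time
itself. One uniform per person drives both the clinical-world and
screened-world survival draws (inverse-CDF coupling), so detection at an
unchanged stage reproduces the clinical death age exactly and an earlier
stage can only postpone death, person by person.

**Counterfactual twin.** Every person's unscreened course (including the
counterfactual clinical diagnosis age) is simulated once and shared by
all strategies. Overdiagnosis — screen detection of a cancer that would
never have been clinically diagnosed before death — and lead time are
therefore exact per-person quantities, not estimates.

## The screening engine

Strategies are declarative (`strategy_definition()`); the ten presets
follow the trial-derived policies: PSA risk bands below 1.5 ng/mL
rescreen at 5 years, 1.5–2.99 at 2 years, work-up at ≥3 ng/mL; DRE
screens annually at 45–75 with suspicious findings referred to
systematic biopsy (a positive DRE also triggers a reflex PSA test, which
is costed). MRI arms interpose an MRI whose positivity depends on
whether significant (GS ≥ 7) disease is present; only MRI-positive men
are biopsied, with combined systematic-plus-targeted biopsy.

Participation has three levers: 75% of men are ever-attenders (drawn
once), attenders accept each rescreen invitation with 95%, and each
biopsy referral is accepted with 65%. Non-attenders are re-invited on
the default recall interval (an open design point; we re-invite rather
than drop them, configurable). Invitations stop at the stop age — an
interval that overshoots it produces no further invitation — and at
diagnosis or death. Symptomatic cases occurring before any screen
detection receive the arm-appropriate work-up: MRI plus combined biopsy
in MRI arms and the no-screening arm, systematic biopsy otherwise.

Management at diagnosis is a grade/stage/age lookup: metastatic disease
gets androgen deprivation/chemotherapy; localized GS <7 enters active
surveillance up to age 75 (PSA+DRE quarterly for two years then
biannually; MRI with combined biopsy at 18 months and 3 years, then
3-yearly — the biopsy periodicity sits inside the guideline range of
12–18 months early, 3 years later); localized GS ≥7 receives radical
treatment up to age 80. Active-surveillance biopsies are counted as
clinically-initiated resource use; *screen-initiated* biopsies are only
those triggered directly by a positive screen.

**Common random numbers.** The cohort pre-draws one uniform per person
per screening round for each stochastic gate (attendance, MRI, biopsy
acceptance, biopsy detection, PSA noise). Every strategy and every
scenario reuses them, so (a) scenarios that touch only costs or
utilities leave all counts bit-identical, and (b) strategy contrasts are
paired, which removes most Monte-Carlo noise from incremental results.

## Economics

The perspective is the statutory health insurance: direct healthcare
costs only, in 2023 euros. The PSA test (25.61 €) and base-case MRI
(500 €) unit costs are fixed from the German fee schedule; the remaining
unit costs (biopsies, radical treatment, androgen deprivation /
chemotherapy and palliative per-year costs, surveillance visits,
follow-up) are documented placeholders of the right order, all
configurable via `cost_schedule()`. Ongoing costs accrue over disease
phases: follow-up for ten years after radical treatment, ADT/chemo over
the metastatic phase, palliative care over the final half-year of a
cancer death. A cured cancer does not progress: the metastatic cost
phase exists only for cancers metastatic at diagnosis or destined to
cause death.

Quality adjustment is multiplicative: an age-specific background utility
(interpolated from population-norm-style values, 0.93 at 45 to 0.74 at
85) times the product of active state utilities. Two utility sets ship —
a disease-specific base-case set and a generally lower generic `eq5d`
set — with identical durations, so swapping sets changes QALYs and
nothing else. Short events (biopsy, the diagnosis month) subtract
event-triggered rectangles against the background; long phases (active
surveillance, treatment year, post-treatment, metastatic, terminal) are
constructed as disjoint intervals with clinical priority
(terminal > metastatic > treatment pathway), which makes the yearly
decomposition exact for the phase part. When a short event overlaps a
phase the loss is computed against the background only — a second-order
approximation (for a biopsy during surveillance the multiplicative and
additive combinations differ by under 0.001 QALYs).

Both costs and (QA)LYs are discounted at 3%/yr from a fixed reference of
age 45, mid-year convention; events before 45 clamp to time zero. LYs
are also counted from 45. Setting the rate to 0 reproduces undiscounted
totals exactly.

## Outcomes, frontier, CEAC

`summarize_per_100k()` scales person-level results to a cohort of
100,000. Diagnostic MRIs of symptomatic cases are costed but not counted
in the screening-MRI tally (the published outcome convention reports
zero MRI events for the no-screening arm while charging symptomatic
cases for MRI).

`efficiency_frontier()` removes strictly dominated strategies, then
extended-dominated ones (ICER not strictly increasing along the
effect-ordered frontier), anchored at the least-cost strategy; ties in
effect break by cost and exact ties collapse. It is validated against an
independent greedy (minimum-ICER gift-wrapping) construction on hundreds
of random instances. Frontiers are computed separately per effect
measure (QALYs, LYs, deaths averted). `ceac_from_draws()` turns
probabilistic-analysis draws into acceptability curves: at each
willingness-to-pay the probability of maximizing net monetary benefit
$\lambda E - C$, ties split equally; the reporting thresholds default to
20k/50k/100k € per QALY with the curve extending to 450k €.

## Calibration

`fit_natural_history()` recalibrates the onset Weibull (shape, scale —
log-parameterized) and the two grade-mixture intercepts against
registry-style targets: age-group incidence (Poisson deviance of target
counts against model-implied expected counts at the registry
person-years) plus grade proportions among diagnoses (multinomial
deviance). Because registries observe incidence *under* the statutory
DRE offer, the calibration cohort is simulated with opportunistic annual
DRE at a configurable uptake (default 20%/yr — an assumption; the
registry period's true uptake is not a published quantity). Every loss
evaluation reuses the same random numbers, making the objective a
deterministic function of the parameters; optimization is Nelder–Mead
with simplex restarts at the incumbent (three rounds by default), which
recovers from premature simplex collapse on the residual Monte-Carlo
surface. Survival and progression parameters are deliberately not fitted
(they are not identified by incidence targets alone).

`validate_mortality()` compares age-specific cancer mortality against
targets with Poisson Monte-Carlo intervals, with no fitting.

## The synthetic-data generator

`make_registry_targets()` plays the role of the external registry
inputs: it simulates a large cohort from a ground-truth parameter set
under background DRE screening, tabulates age-group incidence, grade
mix and cancer mortality, rescales counts to registry-size person-years
(default $10^7$ per 5-year group, ages 40–85), and adds Poisson noise to
the counts. The generating truth ships in an attribute, so parameter
recovery closes the loop: fitting the generated targets from a remote
starting point recovers the onset parameters within a few percent. What
the generator does *not* emulate: registry completeness artefacts,
period/cohort effects, opportunistic PSA testing, and grade migration —
so green tests demonstrate internal consistency of the machinery and
realistic orders of magnitude, not fidelity to any particular national
dataset.

## Sensitivity analyses

`run_dsa()` evaluates named scenarios — each a set of dotted-path
overrides on the base configuration — on one shared cohort: reduced MRI
cost (120 €), no low-risk rescreening with a 4 ng/mL threshold, the same
with 3 ng/mL, discount rates 0/5%, the generic-utility swap, DRE
stopping at 70, MRI cost −50%, raised ADT/chemo costs, and low/high
participation bundles (50/80/50 and 100/100/100 percent). Unresolvable
override paths fail before any simulation.

`run_probabilistic()` draws one joint parameter set per iteration — beta
for probabilities and utilities, gamma for costs, parameterized by mean
and an assumed coefficient of variation (the published point estimates
give no spreads; the deterministic ranges informed them where available)
— and reruns all strategies on a shared cohort. Natural-history
parameters are held fixed, matching the domains the probabilistic
analysis is meant to explore. The reference configuration of the source
analysis is 1000 iterations of one million men; the package default is a
desk-scale 200 × 100,000, and both the iteration count and cohort size
are arguments.

## Problem sizes, numerics, reproducibility

The shipped analyses use: 100,000 persons for strategy comparisons and
qualitative ordering checks; 200,000-person synthetic registries and
100,000-person evaluations (≈150, across three restart rounds) for
calibration; 50,000 persons for distributional tests (life-table
Kolmogorov–Smirnov, incidence-vs-integration). Event ties break by fixed
priority (death before clinical diagnosis before screening events);
screening event comparison operates in continuous age with invitations
capped by a 200-round guard; uniform matrices cover 31 rounds (annual
DRE 45–75 is the widest schedule). All randomness derives from one
master seed through labelled substreams (`derive_seed()`), so any result
— per-100k table, frontier, CEAC — reproduces exactly from
`(configuration, seed)`, and adding a strategy never perturbs another
strategy's stream.

## Known limitations

Treatment does not modify progression dynamics beyond the
survival-curve assignment and the no-progression-when-cured rule; there
is no explicit prostatectomy-vs-radiotherapy split, no biopsy
complication states (a per-biopsy disutility and cost stand in), no
PIRADS-level MRI grading, no opportunistic PSA testing in the background,
and no correlation structure across probabilistic draws. Absolute
per-100,000 outcomes depend on the synthetic default parameterization
and are not estimates for Germany; the machinery — comparisons,
dominance, ICERs, acceptability — is what the package warrants.
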