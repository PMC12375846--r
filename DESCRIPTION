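Package: prostascreen
Title: Microsimulation Cost-Effectiveness Analysis of Prostate Cancer
    Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A person-level natural-history microsimulation of prostate
    cancer (PSA growth, preclinical onset, grade, stage progression,
    clinical presentation, stage-shift survival) together with a screening
    strategy engine covering digital rectal examination and PSA-based
    risk-adaptive screening with or without MRI triage, an economics layer
    producing discounted costs and quality-adjusted life-years, efficiency
    frontier / ICER / CEAC analysis, calibration of onset and grade-mixture
    parameters to registry-style incidence targets, and deterministic and
    probabilistic sensitivity analyses. Ships a synthetic-data module that
    generates life tables and registry-style calibration targets so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
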