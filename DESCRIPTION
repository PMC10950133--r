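Package: hearcue
Title: Cost-Utility Modelling of Hearing-Aid Provision for Age-Related Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multistate Markov cohort model for the economic evaluation of
    hearing-aid provision in age-related hearing loss. Simulates a cohort
    ageing from 55 to 110 years across normal hearing, mild, moderate and
    severe hearing-loss states under three strategies (no treatment, hearing
    aid alone, hearing aid with post-purchase service), with a four-stage
    treatment-uptake journey (care seeking, prescription, purchase,
    compliance), per-cycle cost and utility accrual, and discounting.
    Computes incremental cost-utility ratios and (incremental) net monetary
    benefit, one-way deterministic sensitivity analysis with tornado
    ordering, probabilistic sensitivity analysis with cost-effectiveness
    plane and acceptability curve, and scenario grids over cost mixes and
    dropout/compliance assumptions. Includes synthetic generators for
    gender-specific life tables (Gompertz-Makeham hazards) and hearing-loss
    progression models calibrated to prevalence targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
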