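Package: pctcea
Title: Cost-Effectiveness of Baseline Procalcitonin Testing in Hospitalized COVID-19 Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model for evaluating the
    cost-effectiveness of baseline procalcitonin (PCT) testing to guide
    antibiotic prescribing in people hospitalized with COVID-19. Provides a
    seeded synthetic patient-level cohort generator calibrated to published
    group summaries, length-of-stay derivation and exclusion rules, free-text
    antibiotic name normalization with two-tier unit-price matching and
    antimicrobial-resistance surcharges, per-patient QALY and cost accrual
    with utility decrements and life-table discounting, and propensity-weight
    aware bootstrap uncertainty including incremental cost-effectiveness
    ratios, cost-effectiveness planes and acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
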