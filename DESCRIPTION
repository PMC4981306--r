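Package: oabcea
Title: Cost-Effectiveness of Test-Treat Strategies for Refractory
    Overactive Bladder and Mixed Urinary Incontinence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing diagnostic test-treat
    strategies (urodynamics, bladder-wall-thickness ultrasonography, and
    clinical history, alone or conditional on history) for women with
    refractory overactive bladder or urgency-predominant mixed urinary
    incontinence. Provides parameter-distribution fitting (Beta, Gamma,
    Dirichlet), a synthetic cross-sectional cohort generator for test
    accuracy and prevalence inputs, decision-tree construction and
    evaluation over a five-year horizon with discounting, incremental
    cost-effectiveness frontiers with dominance handling, probabilistic
    sensitivity analysis, cost-effectiveness acceptability frontiers, and
    expected value of perfect information at per-person and population
    level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
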