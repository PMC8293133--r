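Package: radcua
Title: Cost-Utility Analysis of Prostate Radiotherapy Modalities with a
    Cohort Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) model for the cost-utility
    comparison of six radiation treatment modalities for intermediate-risk
    prostate cancer: conventionally and hypofractionated IMRT, HDR
    brachytherapy combined with IMRT, HDR and LDR brachytherapy
    monotherapy, and stereotactic body radiotherapy. Provides a
    radiotherapy micro-costing calculator, half-cycle-corrected discounted
    QALY and cost accumulation over a 20-year horizon in 6-month cycles,
    probabilistic sensitivity analysis with beta/gamma parameter
    distributions, sequential incremental cost-utility (ICUR) analysis
    with strict and extended dominance, cost-effectiveness acceptability
    curves, and a synthetic parameter generator calibrated to published
    probabilistic averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
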