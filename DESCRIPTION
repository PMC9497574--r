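Package: dcmscreen
Title: Stratified Screening Tool Construction for Degenerative Cervical
    Myelopathy from Grip-and-Release and Grip-Strength Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates a sex- and age-stratified diagnostic
    support tool for degenerative cervical myelopathy (DCM) from two
    negatively-oriented bedside hand tests: the 10-second grip and release
    test (GRT) and maximal grip strength. Provides per-stratum empirical ROC
    analysis with Youden-index cutoff selection, an OR-combination (parallel)
    screening rule, confusion-table performance metrics with likelihood
    ratios, Wilcoxon rank-sum group comparisons, and a binormal synthetic
    cohort generator parameterized by published stratum means and standard
    deviations so the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
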