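Package: voxmem
Title: Construction, Calibration, and Scoring of Voice Learning and Memory Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for building and calibrating three-alternative
    forced-choice (3AFC) voice learning and recognition tests. Places
    speakers in a three-dimensional acoustic voice space (fundamental
    frequency, formant dispersion, harmonics-to-noise ratio), searches the
    space for equilateral voice triplets stratified by acoustic similarity,
    assembles the three-phase test blueprint (learning, repetition,
    testing) under sentence-novelty and position-balancing constraints, and
    provides a marginal-maximum-likelihood item response theory engine
    (Rasch and two-parameter logistic models) with expected a posteriori
    ability estimation, empirical marginal reliability, item fit, test
    information, and differential item functioning. A stepwise
    item-selection workflow, respondent scoring with omission handling and
    norm-referenced extreme-score screening, and seeded simulators for
    voices and respondents make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
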