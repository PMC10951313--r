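Package: optocoupling
Title: State-Dependent Analysis of Targeted Photostimulation Effects on
    Visual Detection and Cortical Network Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for all-optical experiments in which co-tuned
    ensembles of visual cortical neurons are photostimulated while mice perform
    a contrast-varying detection task. Provides engagement-state indexing from
    pre-trial pupil size and population synchrony, fixed-asymptote Weibull
    psychometric fits and d-prime, neuropil correction and windowed delta-F/F
    response extraction, hit:miss ratio-matched response estimation,
    cross-validated contrast-response similarity binning with suppression-slope
    analysis, spatial influence profiles, and a bootstrap/shuffle statistic
    coupling network changes to behavioral changes. A synthetic-session
    generator with recorded ground truth emulates the data structure of such
    experiments so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
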