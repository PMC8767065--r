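Package: excitokit
Title: Quantification of Glutamate Excitotoxicity Endpoints in Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for single-cell excitotoxicity experiments in
    primary neuronal cultures: classification of delayed calcium deregulation
    (DCD) in ratiometric calcium-imaging traces, lag-DCD estimation by tangent
    intersection, post-washout recovery indices, mitochondrial-potential
    (Rhodamine 123) recovery slopes and FCCP/post-glutamate AUC ratios,
    plate-format oxygen-consumption (OCR) respiration metrics, live/dead and
    kinetic MTT viability endpoints, soma-area morphometry, and a
    distribution-gated group-comparison ladder. Includes a seeded synthetic
    cohort generator that emulates the statistical structure of such
    experiments so every estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    lme4,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
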