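Package: mseeg
Title: Multiscale Entropy Analysis of EEG Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying electroencephalographic (EEG) complexity
    with multiscale entropy: coarse-graining and sample entropy per electrode
    and time scale, spectral band power, behavioral scoring for
    metacontrol/creativity designs (adaptive scores, median splits, rater
    reliability), aggregation of entropy over scalp functional networks, and a
    split-plot statistical battery with Greenhouse-Geisser correction.
    Includes a seeded synthetic-cohort generator (EEG epochs, trial-level
    behavior, multi-rater originality scores) so the full pipeline can be
    exercised and validated without subject data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
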