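Package: hdspeech
Title: Digital Speech Biomarkers for Huntington Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and statistical analysis of digital speech biomarkers
    for Huntington disease from timed speech tasks (passage reading, counting
    forward, counting backward). Computes phonatory, articulatory, prosodic and
    intelligibility features from audio recordings and word-level timed
    transcripts, including pause/timing measures, autocorrelation-based
    fundamental-frequency statistics, Bark-band loudness, letter-encoded
    dynamic-time-warping similarity and dual-transcript intelligibility, and
    counting-task accuracy scores. Provides pairwise group contrasts with
    Cohen's d, clinical-score correlations, leave-one-subject-out random-forest
    classification and regression, and a synthetic cohort and recording
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
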