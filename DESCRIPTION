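Package: stepfret
Title: Stepwise Nucleosome Translocation Analysis from Single-Molecule FRET
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing single-molecule FRET (smFRET) recordings of
    ATP-dependent chromatin remodeling. Implements trace selection by one-step
    photobleaching, background subtraction and proximity-ratio FRET
    computation, entry-/exit-side movement classification, two complementary
    step-detection algorithms (chi-square-minimization plateau fitting and a
    Gaussian-emission hidden Markov model), a missed-step Gaussian mixture
    model for step-size histograms with a globally shared peak width,
    FRET-versus-linker-length calibration and conversion of FRET step sizes
    to base pairs, and detection-censored exponential pause-lifetime analysis.
    A seeded synthetic-trace generator with ground-truth annotations supports
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
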