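Package: pausegate
Title: Virtual Closed-Loop Visual Stimulation for Intermittent Insect
    Locomotion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates tethered-insect virtual-reality experiments in which a
    random-dot kinematogram is gated by the animal's detected motion state
    (open loop, in phase, or out of phase with walking). Provides a
    generative pause-and-go agent with pause-weighted visual evidence
    accumulation, threshold-plus-debounce motion detection, fictive-path
    reconstruction from trackball rotation streams, walk/pause bout
    segmentation with intermittency metrics, exact and permutation
    Mann-Whitney group comparisons, and an experiment runner for
    between-subject and within-subject designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
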