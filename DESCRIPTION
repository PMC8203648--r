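Package: ofmrinet
Title: Stimulus-Driven Optogenetic fMRI Analysis and Differential
    Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for stimulus-driven (optogenetic) BOLD fMRI
    in small animals: construction of heat/laser/co-stimulation paradigms
    and two-gamma HRF design matrices, temporal resampling and smoothing,
    voxel-wise GLM with per-subject FDR thresholding, atlas-based region
    time courses, event-related averaging with repeated-measures group
    comparison, and a differential functional-connectivity procedure
    (global-mean removal, Fisher-z pooled Pearson matrices, fixed-edge-count
    dual-channel thresholding, per-edge t-tests, signed net-FC aggregation
    over composite nodes, and pseudo-directioning by a structural prior).
    Includes a seeded synthetic-cohort generator with planted regional
    response amplitudes and inter-regional couplings so every stage is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
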