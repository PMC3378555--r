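Package: retinowm
Title: Retinotopic Analysis of Spatial Working Memory Activity in Early Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how task
    instructions redistribute delay-period BOLD activity across the
    retinotopic maps of visual areas V1, V2 and V3.  Provides a synthetic
    fMRI generator (retinotopically organised voxel sheets, rotating-wedge
    and expanding-ring mapping runs, two-stimulus spatial working-memory
    sessions with injectable delay effects), phase-encoded retinotopy by
    peak lagged cross-correlation, visual-field segment ROIs, a
    concatenated-segment delay-period general linear model, and
    repeated-measures group statistics, together with calibration and
    power-simulation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods, SummarizedExperiment
Imports: stats, utils, grDevices, S4Vectors, car, jsonlite, yaml, withr,
    rlang, ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
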