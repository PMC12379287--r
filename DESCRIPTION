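Package: gvscan
Title: Collapse-Based Ultrasound Imaging and Quantification of Gas-Vesicle Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and quantification pipeline for
    collapse-based ultrasound imaging of gas-vesicle-expressing bacterial
    biosensors. Provides acquisition-schedule and stage-scan planning,
    synthetic multi-frame acquisition stacks with correlated speckle and
    breathing motion, BURST (first minus last collapsing frame) and BURST*
    (second minus first) reconstruction with motion screening, transverse
    stitching into 3-D volumes with GI-tract ROI masking, signal-to-background
    and decibel quantification with shared display normalization,
    depth-integrated maps, overlays and ex vivo length profiles, Hill
    dose-response fitting with maximal fold change and detection limits,
    anchored relative-patch-opacity screening statistics, and supporting
    assay calculations (CFU per gram, flow-cytometry gating summaries,
    Freedman-Diaconis binning, internal-standard chromatography calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
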