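Package: cellmapr
Title: Post-Segmentation Analysis of Bacterial Single-Cell Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Standardizes cell-outline, fluorescent-spot, object and image
    data produced by heterogeneous bacterial segmentation and spot-detection
    programs into one data model, computes cell-relative coordinates via
    minimum-area bounding-box orientation, and provides population and
    time-lapse analytics: equal-count length-group projections, demographs,
    kymographs, division detection from length trajectories,
    percentage-of-division alignment, lineage trees, and hierarchical
    clustering of fluorescence-versus-division profiles. Includes a
    synthetic-data generator (rod/coccus/ovococcus meshes, Gaussian-spot
    images with Poisson noise, exponentially growing and dividing tracks)
    so every analysis path can be exercised without external downloads, and
    a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    grDevices
Suggests:
    ape,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
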