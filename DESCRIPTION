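Package: osteorms
Title: Quantifying Osteophyte Depiction Accuracy in 3D Ultrasound and CT
    Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A validation pipeline for scoring how faithfully imaging-derived
    bone-surface models depict knee osteophytes against a high-resolution
    structured-light-scan ground truth. Provides triangle-mesh input/output
    and exact point-to-surface distance queries, fiducial (landmark) and
    iterative-closest-point rigid registration including the three-way
    SLS/3D-US/CT alignment protocol, per-region RMS surface-distance scoring
    with colour-coded topographic error maps, Welch unequal-variance
    comparison of modality error distributions, and a synthetic condylar
    phantom with graded osteophytes plus simulators for the three imaging
    modalities so the entire pipeline can be exercised without cadaveric
    specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    vctrs,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
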