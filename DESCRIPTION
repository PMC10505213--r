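Package: doct
Title: Dynamic Optical Coherence Tomography Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes three-dimensional dynamic optical coherence tomography
    (D-OCT) contrasts from repeated B-scan time sequences: the logarithmic
    intensity variance (LIV, dB^2) and the late/early OCT correlation decay
    speeds (OCDS_l, OCDS_e, 1/ms) obtained from the temporal autocorrelation
    of dB-scaled intensity. Renders HSV pseudo-color images (hue = dynamics
    metric, value = OCT intensity), segments spheroids from intensity volumes
    with automated well-plate removal, and quantifies spheroid volume, mean
    dynamics and necrotic-cell ratios, with exact Mann-Whitney group
    comparisons. Includes a dynamic-speckle spheroid phantom generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    igraph,
    tiff,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
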