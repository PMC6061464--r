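Package: stonequant
Title: Quantitative Single-Energy CT Analysis of Urinary Stones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Operator-independent quantification of urinary stones in
    unenhanced single-energy CT volumes. Segments a stone by half-of-peak
    thresholding with 3D hole filling, computes attenuation histogram
    statistics, applies a scaled 3D Laplacian texture filter to obtain the
    peak point Laplacian (ppLapl), derives alpha-shape volume and sphericity,
    and classifies pure uric-acid stones from a peak attenuation / peak point
    Laplacian decision rule evaluated with exact binomial confidence
    intervals. Includes a synthetic phantom generator with known ground
    truth, minimal NIfTI-1 and DICOM readers, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
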