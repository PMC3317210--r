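Package: cryocount
Title: Detection and Model-Based Counting of Fluorescent Cell Clusters
    in Cryo-Imaging Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for enumerating fluorescently labeled cells in
    low-resolution cryo-imaging volumes, where single cells are
    approximately one pixel wide and cell boundaries cannot be resolved.
    Implements next-image subtraction of subsurface fluorescence,
    background removal by grayscale morphological reconstruction,
    red/green ratio thresholding, hysteresis segmentation with 3D
    connected-component labeling, knowledge-based false-positive
    rejection, and model-based counting of cells per cluster by fitting
    superpositions of fixed-shape, fixed-intensity pixel-integrated
    Gaussians. Includes a synthetic phantom generator with ground truth
    and an evaluation harness (contingency tables, Fleiss' kappa,
    sensitivity/specificity, total-count error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
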