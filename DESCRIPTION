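Package: fibrequant
Title: Quantification of 3D Fibrous Tissue Architecture from Microtomographic Volumes
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the hierarchical fibrous architecture of soft
    tissues (vocal folds in particular) from reconstructed X-ray
    microtomography volumes: per-voxel fibre orientation by 3D structure
    tensors, orientation distribution functions and second-order orientation
    tensors, fibre waviness (spatial period and amplitude) in the orientation
    eigenframe, cross-section morphometry (perimeter, area, equivalent
    diameter, roundness, centroid tracking), local thickness maps of
    segmented layers, and bead-marker based tissue elongation. Includes a
    synthetic phantom generator (wavy fibre networks, cylinders, slabs,
    bead markers, imaging noise) with exact ground truth so the whole
    pipeline is testable without tomography data, and a small CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
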