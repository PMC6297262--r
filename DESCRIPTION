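Package: jacmorph
Title: Longitudinal Jacobian-Map Morphometry for Small-Animal Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for longitudinal voxel-based (tensor-based)
    morphometry of three-timepoint structural MRI in rodents. Generates
    synthetic phantom cohorts with analytically known deformations,
    preprocesses scans (denoising, bias-field correction, skull stripping,
    rigid alignment, histogram matching), performs dense diffeomorphic
    registration and group-wise template construction, converts deformation
    fields into log-Jacobian determinant maps, runs voxel-wise one-tailed
    permutation tests with Monte-Carlo cluster-extent correction, and
    quantifies per-ROI expansion/shrinkage overlap against a label atlas,
    classifying regional change as reversible or enduring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    withr,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
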