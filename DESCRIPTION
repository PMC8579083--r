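Package: metrano
Title: Automated Brain Metastasis Detection, Segmentation and RANO-BM
    Response Assessment on 3D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computer-aided detection (CAD) pipeline for brain metastases
    on contrast-enhanced 3D T1-weighted MRI. Provides gray-matter anchored
    intensity normalization, brain masking and cropping, coarse 3D lesion
    detection and fine per-lesion 2D segmentation with compact trainable
    encoder-decoder (U-Net style) networks under a Dice loss, per-lesion
    volumetry and longest axial diameter measurement, similarity (rigid plus
    isotropic scale) registration of serial scans with lesion-level matching,
    and automated treatment-response categorization under modified RANO-BM
    criteria with one-dimensional and volumetric rules. Includes a seeded
    synthetic phantom generator with exact lesion ground truth for testing
    and validation, plus lesion-wise detection metrics, Dice coefficients,
    weighted-kappa agreement and exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
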