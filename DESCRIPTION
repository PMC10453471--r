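Package: spineseg
Title: Two-Stage Spine Segmentation and Vertebra Recognition for CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage convolutional pipeline for spine analysis in computed
    tomography: a 2D attention residual U-Net with cascaded hierarchical atrous
    spatial pyramid pooling for binary spine segmentation, followed by a 3D
    multi-view recognition network that fuses per-slice features from the
    axial, sagittal and coronal planes to assign per-vertebra labels. Includes
    NIfTI input/output with canonical reorientation, Hounsfield-unit
    preprocessing (smoothing, clamping, four normalization modes, resizing),
    joint image/label augmentation, overlap metrics (Dice, IoU, precision,
    recall), a seeded synthetic spine-phantom generator, and a reproducible
    training and evaluation harness. All network layers carry hand-derived
    forward and backward passes backed by compiled convolution kernels, so the
    full pipeline trains deterministically on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
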