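Package: craniofill
Title: Two-Stage Volumetric Deep Learning for Cranial Implant Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs defective three-dimensional skull voxel models and
    extracts cranial implant geometry with a two-stage convolutional system:
    a dilated 3D U-Net that inpaints a low-resolution defective skull, and a
    two-input resolution-enhancement network that restores the repaired model
    to the native grid. Includes synthetic cranial-vault phantoms, a
    parametric defect-mask simulator with rotation augmentation, binary
    cross-entropy/Adadelta training at desk scale, Sorensen-Dice and directed
    Hausdorff evaluation, cranial vault asymmetry indices (ACVAI/PCVAI),
    volume I/O for NIfTI, NRRD and raw-uint8 grids, and implant
    post-processing (tolerance scaling, morphological opening, connected
    component filtering, STL export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
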