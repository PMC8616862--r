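Package: uncoverweight
Type: Package
Title: Virtual Uncovering and Weight Estimation of Covered Patients from
    Depth-Derived Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage volumetric pipeline for contactless body-weight
    estimation of patients lying in bed, including patients occluded by a
    blanket. Depth frames are back-projected to metric point clouds,
    voxelized into a fixed cuboid occupancy grid, "virtually uncovered" by
    a 3D U-Net trained on paired covered/uncovered frames, and regressed
    to weight by a compact 3D convolutional network. Ships a synthetic
    in-bed scene simulator (primitive-based bodies with analytic weight
    ground truth, height-field blanket drape, pinhole depth rendering) so
    every stage is trainable and testable without access to clinical
    recordings, plus Dice / surface-distance / MAE evaluation tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite,
    Rcpp,
    EBImage,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'uncoverweight-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'depth.R'
    'voxel.R'
    'metrics.R'
    'nn-layers.R'
    'losses.R'
    'weightcnn.R'
    'unet.R'
    'training.R'
    'evaluate.R'
    'io.R'
    'pipeline.R'
    'scene.R'
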