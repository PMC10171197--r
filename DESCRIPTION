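Package: supervent
Title: Super-Voxel CT Ventilation Imaging from a Single Exhale CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates surrogate lung ventilation images from a single
    exhale-phase CT and a lung mask using spacing-aware 3D SLIC super-voxel
    segmentation, density gating and Gaussian-distance interpolation of
    super-voxel mean densities (CTVI_SVD). Also provides the conventional
    deformable-registration comparators (HU density-change and Jacobian
    determinant ventilation from a supplied deformation field), their
    super-voxel-smoothed variants, an evaluation suite (voxel-wise Spearman
    correlation, 66th-percentile high/low function split, Dice overlap,
    super-voxel-number sweeps with paired t-tests), and a synthetic thorax
    phantom generator so the entire pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
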