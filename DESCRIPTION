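Package: rtfe
Title: Real-Time Micro-Finite-Element Adaptive Loading for Bone Defect Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based micro-finite-element (micro-FE) analysis of healing
    bone defects and real-time adaptive-loading planning. Converts 3-D mineral
    density volumes (micro-CT style) to voxel-wise linear-elastic hexahedral
    meshes via a multi-density Young's modulus ladder, solves the compressive
    displacement problem with a matrix-free preconditioned conjugate-gradient
    solver, and derives the tissue-scale effective-strain distribution. An
    adaptation layer rescales strains to any applied force, matches the
    distribution to a reference target (median 700 microstrain) by minimizing
    the two-sample Kolmogorov-Smirnov statistic with a one-dimensional
    Nelder-Mead search, and screens the chosen load against refracture risk by
    iterative 2 N downscaling until fewer than 50 bone voxels are at or above
    10,000 microstrain. A synthetic phantom generator produces osteotomized
    femur-like volumes and longitudinal healing series with ground-truth masks
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
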