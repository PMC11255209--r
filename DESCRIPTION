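Package: bonefail
Title: Voxel-Based Finite-Element Failure Load Estimation from CT Bone Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how CT bone segmentation quality propagates
    into simulated bone strength. Provides synthetic CT phantoms of femur- and
    vertebra-like objects with embedded density-calibration rods, a
    pre-processing chain (resampling, bilateral splitting and mirroring,
    affine co-registration, intensity normalisation), threshold-based
    segmentation with morphological post-processing and perturbation
    operators, QCT density calibration and density-to-elasticity laws,
    a voxel-based hexahedral finite-element solver with an
    elastic-perfectly-plastic constitutive model for displacement-controlled
    compression to failure, segmentation-agreement metrics (Dice, Hausdorff),
    and an orchestrated sensitivity study comparing failure loads across
    eroded and dilated segmentation variants with Friedman/Dunn statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
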