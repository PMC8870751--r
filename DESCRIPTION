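Package: kneemorph
Title: 3D Morphometric and Densitometric Assessment of Knee Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis workflow for assessing knee-joint cartilage condition
    from 3D reconstructions. Generates synthetic knee compartments (Hounsfield
    unit voxel volumes plus triangulated cartilage shells) with known ground
    truth, computes densitometric features (HU statistics, phantom-calibrated
    bone mineral density, mask volumes and iso-surface areas) and
    mesh-morphometric features (surface-to-surface wall thickness, discrete
    Gaussian curvature by angle deficit, through-hole detection with best-fit
    ellipse grading), derives area-normalized per-element summary statistics
    including threshold-exceedance fractions, and runs nonparametric group
    comparisons (Shapiro-Wilk, Kruskal-Wallis, Dunn post hoc) and tree-ensemble
    classification (decision tree, random forest, gradient boosting) with
    cross-validated metrics and feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    rpart,
    randomForest,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
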