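Package: gaitnormals
Title: Gait Symmetry Indices from Body Surface Normals in Depth Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures human gait symmetry from frontal-view depth-map
    sequences of a subject walking on a treadmill. Body pixels are
    reprojected to a 3D point cloud with the pinhole model, per-point
    surface normals are estimated from neighborhood covariance
    eigen-structure, normals are accumulated over a 2x2 silhouette grid,
    and left-right angle features on the transverse, sagittal and coronal
    anatomical planes are aggregated into frame-based, segment-based and
    variance-weighted combined symmetry indices. Includes a synthetic
    articulated-body depth renderer for labelled normal and asymmetric
    walking sequences and an ROC/AUC evaluation harness for abnormal gait
    detection, with pooled and leave-one-subject-out schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
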