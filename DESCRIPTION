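Package: multiatlas
Title: Multi-Atlas Landmark Annotation and Morphometric Evaluation for 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated anatomical landmark annotation of 3D
    volumetric images (e.g. microCT) by atlas-based label transfer.
    Implements unbiased population-atlas construction, probabilistic
    atlases and probability surfaces, deformable multi-resolution
    registration with dense displacement-field transforms, label fusion
    by shape-based averaging, majority vote and STAPLE, single-atlas,
    improved single-atlas and multi-atlas annotation pipelines with
    template selection by k-means clustering and a distance-threshold
    outlier detector, and a geometric-morphometrics evaluation layer
    (generalized Procrustes analysis, Goodall F test, EDMA form-matrix
    test, Box M test on principal-component scores, rank tests and
    centroid-size regressions). A synthetic-study generator produces
    populations of smoothly deformed 3D shapes with ground-truth
    landmarks and simulated repeated manual annotations so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
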