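Package: mprreg
Title: Automatic Standard-Plane Regression for 3D Orthopedic CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regression of the axial, (semi)coronal and sagittal multiplanar
    reconstruction (MPR) planes of 3D cone-beam CT volumes of orthopedic body
    regions. Provides the plane parameterization (center plus orthonormal
    in-plane frame), four bounded rotation representations (Euler sine/cosine,
    unit quaternion, and two 6D Gram-Schmidt variants), a composed
    single-interpolation spatial augmentation pipeline with mirror handedness
    handling, sigmoid-window intensity normalization, a convolutional pose
    regressor (baseline, single-head and multihead multitask variants) trained
    with minibatch gradient descent, an orthogonality-restoring postprocessing
    step, a weighted plane-error score with fold aggregation, and a synthetic
    phantom generator with analytically known ground-truth planes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
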