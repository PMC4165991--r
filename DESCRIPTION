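Package: usrecon
Title: Freehand 3D Ultrasound Volume Reconstruction by Kernel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs regular 3D volumes from tracked freehand 2D
    B-scan ultrasound sweeps. Pixels of each pose-tracked B-scan are
    bin-filled into a voxel grid and the full volume is then estimated by
    local polynomial kernel regression (orders 0-2, Gaussian kernel) over
    the sparse sample cloud. Classical voxel-nearest-neighbour,
    pixel-nearest-neighbour (with hole filling) and inverse-distance
    weighted reconstructors are included as baselines, together with a
    leave-one-slice-out root-mean-square-error evaluation protocol, a
    synthetic tracked-sweep simulator with pose jitter and speckle-like
    noise, and readers/writers for MetaImage and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    utils,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
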