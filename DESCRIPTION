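Package: oct4dmotion
Title: Spatio-Temporal Deep Learning Motion Estimation for 4D OCT Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthetic 4D optical coherence tomography (OCT) motion benchmark
    and estimation toolkit. Simulates speckle-textured tissue phantoms and
    acquires 32x32x32 volume sequences along smooth spline drift trajectories
    with exact sub-voxel ground truth; implements five convolutional
    architectures for translation regression (two-path and multi-path 3D
    networks, full 4D networks built on a from-scratch differentiable 4D
    spatio-temporal convolution), a temporally regularized mean squared error
    training objective, and an evaluation suite with MAE, rMAE, average
    correlation coefficient, magnitude-binned errors, paired Wilcoxon
    comparisons, and rotation/distortion robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
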