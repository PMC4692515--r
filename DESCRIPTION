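Package: motionmvpa
Title: Multi-Voxel Pattern Decoding of Imagined Motion Direction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested end-to-end pipeline for decoding the direction of
    imagined visual motion from high-resolution fMRI-like data. Simulates
    a blocked four-direction imagery paradigm with ground-truth
    direction-selective voxels, hemodynamic convolution, run-wise drift and
    gaze traces; preprocesses runs (Fourier-basis high-pass filtering,
    run-wise z-scoring, trial feature extraction); performs one-vs-one
    four-class linear support-vector decoding with fold-wise ANOVA-F feature
    selection, leave-one-run-out cross-validation and scrambled-label
    permutation inference; maps local information with a volumetric
    searchlight (chi-square confusion tests, FDR thresholding); fits
    univariate general linear models with a two-gamma hemodynamic response
    function and one-vs-all contrasts; and screens eye-movement confounds
    with velocity-threshold saccade detection, circular statistics and
    minimum-volume enclosing ellipses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
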