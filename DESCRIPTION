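Package: trusseg
Title: Automated 3D Prostate and Zonal Segmentation for Transrectal Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for three-dimensional segmentation of the
    prostate gland and its zones (transition and peripheral zone) from
    transrectal B-mode and contrast-enhanced ultrasound volumes. The pipeline
    resamples a 3D volume into 2D radial planes about the probe axis, segments
    each plane with a small context-aware encoder-decoder convolutional
    network (two output channels: prostate and transition-zone probability),
    reconstructs 3D label masks by cylindrical interpolation, and evaluates
    segmentations with overlap (Dice, IoU), volume (relative volume
    difference) and surface (mean surface distance, Hausdorff) metrics with
    per-case aggregation and confidence intervals. Includes a synthetic
    ultrasound phantom generator with exact ground truth for end-to-end
    testing, and Bland-Altman / R-squared volume agreement statistics
    including PSA density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
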