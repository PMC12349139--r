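Package: fallsynth
Title: Synthetic Accelerometer Fall Data Generation and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for enlarging the scarce fall class in wearable
    triaxial-accelerometer datasets and measuring whether the enlargement
    helps. Implements three generation strategies (classic augmentations:
    jittering, cubic-spline magnitude warping, random sensor rotation; a
    denoising diffusion probabilistic model with a 1D convolutional U-Net
    denoiser adapted to variable-length trials by last-value padding and
    RMSNorm; and conversion of 3D pose keypoint trajectories to virtual
    accelerometer streams via discrete second differences), a five-metric
    synthetic-data quality suite (context Frechet distance, discriminative
    score, predictive score, Jensen-Shannon divergence, averaged
    Kolmogorov-Smirnov D), and a windowed LSTM fall-detection training and
    evaluation protocol with subject-wise splits and class balancing. A
    seeded signal simulator produces ADL and fall trials with free-fall
    dip and impact-spike morphology so the whole pipeline is exercisable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
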