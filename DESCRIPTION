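Package: squatcheck
Title: Squat Posture Assessment from 2D Pose Keypoint Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses squat exercise form from frontal-view 2D skeleton
    keypoint streams (OpenPose-compatible JSON). Implements the full
    pipeline: keypoint subsetting to ten torso and leg joints, hip-centered
    torso-length normalization anchored on an upright reference frame,
    Gaussian trajectory smoothing, per-frame delta features, and a binary
    posture classifier combining temporal 1D convolutions with a
    bidirectional LSTM (plus convolution-only and LSTM-only ablation
    variants), trained with Adam and dropout. Includes a kinematic squat
    simulator generating labeled correct and defective repetitions
    (shallow depth, knee valgus, forward lean, asymmetry) for training and
    validation, and app-side feedback logic: score thresholding, good/bad
    verdicts, and 0-10 session scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
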