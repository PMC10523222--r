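---
title: "Squat posture assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Squat posture assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatcheck)
```

This vignette explains what the package computes and why the pieces are
shaped the way they are: the preprocessing model and its assumptions, the
classifier and its hyperparameters, what the kinematic simulator does and
does not emulate, and the numerical and design decisions that were
genuinely open.

## The preprocessing model

The input is a per-frame stream of named 2D keypoints in image
coordinates (origin top-left, y grows downward) at a nominal 30 fps, as a
frontal-view pose estimator emits them. The pipeline applies, in order:

1. **Joint subsetting.** Of the 25-landmark skeleton only 10 joints are
   kept — neck, mid-hip, shoulders, hips, knees, ankles — because arm,
   head and foot positions carry little information about squat form.
   The fixed joint order defines the 20-channel feature layout (per
   joint: x then y), recorded in every model checkpoint so that a model
   cannot silently be applied to differently ordered features.
2. **Gap interpolation.** Pose estimators drop joints; interior gaps are
   filled linearly between the nearest observed frames and edge gaps copy
   the nearest observation. A joint missing in more than 20% of frames
   aborts with a data-quality error: beyond that, interpolation fabricates
   motion rather than bridging noise. Observed frames are never altered.
3. **Reference-frame normalization.** An upright frame is selected from
   the first 30 frames (~1 s) as the one maximizing the projected
   mid-hip-to-neck (torso) distance — the frontal torso projection is
   longest when the subject stands straight before a level camera; ties
   break to the earliest frame. From that frame a transform `p ↦ (p +
   translation) · scale` is fitted mapping the mid-hip to (0, 0) and the
   torso length to 1, then applied to *all* frames. The family is
   translation + isotropic scale only, **no rotation**: torso lean is a
   form defect the classifier must see, and rotation alignment would
   erase it. Consequently the features are provably invariant to global
   translation and uniform rescaling of the raw pixels (the tests assert
   ≤ 1e-9 relative change under ±1000 px shifts and ×0.1/×10 scaling) and
   deliberately *not* invariant to rotation (also asserted, to guard
   against over-normalizing).
4. **Gaussian smoothing.** Each joint's x- and y-series is convolved with
   a normalized discrete Gaussian of SD 1 frame, truncated at radius
   ⌈4σ⌉ and renormalized, with reflected boundaries. This suppresses
   single-frame estimation jumps while leaving the ~2 s squat motion
   intact. Smoothing and the (linear) normalization commute, so their
   order is immaterial; the package normalizes first and a test pins the
   commutation down.
5. **Delta features.** The model consumes per-frame *changes* of the
   normalized positions: `k` frames become a `(k−1) × 20` matrix whose
   row `t` is `position(t+1) − position(t)`. A motionless recording is
   exactly all zeros, and cumulative summation recovers the normalized
   trajectory — both are tested identities.

Working in image coordinates end to end (y down) is safe because the
normalization makes the classifier indifferent to the convention; it is
documented rather than converted.

## The classifier

The delta tensor is classified by a hybrid temporal network:

| block | shape | notes |
|---|---|---|
| Conv1D × 3 | kernels 5, 3, 3; filters 32, 64, 64 | valid padding, stride 1, ReLU; time shrinks by 8 |
| BiLSTM | 64 outputs | 32 hidden units per direction; final states concatenated |
| Fully connected | 32 units | ReLU |
| Softmax | 2 classes | correct / incorrect |

Training: Adam (learning rate 0.003, β₁ = 0.9, β₂ = 0.999), dropout 0.3
after each convolution block and after the fully connected layer (active
only during training), softmax cross-entropy loss, early stopping on
validation accuracy with patience 10 (defaults; the experiment scripts
use patience 8 with a 50-epoch cap), best-validation weights restored. A
grid-search helper trains every combination of supplied hyperparameter
values on a fixed split and returns the validation-accuracy argmax with
the full result table.

Ablation variants share the harness: `conv_only` summarizes the
convolution stack by temporal mean-pooling before the fully connected
layer; `lstm_only` feeds the 20-channel deltas straight into the BiLSTM.

Design points that were genuinely open, and the choices made:

* **"64 outputs" of the bidirectional LSTM** is read as *total* output
  width — 32 per direction, concatenated — the reading consistent with
  the fully connected layer's 64-wide input.
* **Convolution padding** is `valid`: progressive temporal aggregation
  without zero-padding artifacts. This sets the minimum input at 9
  feature rows (a 10-frame sequence); shorter inputs are refused with the
  minimum named.
* **Sequence summarization** into the fully connected layer is the
  concatenated final hidden state of each LSTM direction.
* **Variable-length sequences** are handled by computing gradients per
  sequence and averaging over the minibatch (default 32), which is
  mathematically identical to zero-padding with a length mask but needs
  no mask bookkeeping.
* The network, backpropagation (including through time) and Adam are
  implemented in R within the package; the analytic gradients of every
  variant are checked against central finite differences in the test
  suite (relative error ≤ 1e-4 on random probes).

Evaluation reports accuracy, precision and recall from the 2×2 confusion
matrix with "correct posture" as the positive class, validated in the
tests against a brute-force counting oracle on random prediction/label
vectors.

## The squat simulator

Real squat-video keypoint datasets involve human subjects and are rarely
shareable, so the package generates its own: a planar kinematic chain —
two legs (shank + thigh) and a torso — projected as a frontal camera
would see it. Knee flexion θ(t) follows a cosine-eased profile reaching
the peak depth at mid-repetition; shank and thigh tilt symmetrically by
θ/2 so the hip stays over the ankle, making the frontal-view hip height
`(shank + thigh)·cos(θ/2)`. Sagittal forward lean appears, as a front
camera would render it, as torso foreshortening (`torso·cos(lean)`).
Per-frame Gaussian pixel jitter emulates pose-estimator noise, and an
optional dropout probability marks joints undetected to exercise the
interpolation path.

Defect modes and the documented thresholds at which a repetition is
labeled incorrect (conventions of this artifact, chosen so labels are
reproducible from the generated coordinates):

| defect | mechanism | incorrect when |
|---|---|---|
| `shallow_depth` | achieved depth = `depth_deg·(1 − magnitude)` | achieved depth < 70° |
| `knee_valgus` | knees move medially by `magnitude · hip_width`, ∝ flexion | magnitude > 0.15 |
| `forward_lean` | torso tilts by `magnitude`° at peak, foreshortened frontally | magnitude > 20° |
| `asymmetric` | left/right peak flexion split by `magnitude`° | magnitude > 15° |

Label consistency is testable from the data alone: peak flexion is
recovered from coordinates as `2·acos(h_squat / h_stand)` using the
hip-above-ankle heights, valgus as the knees' medial travel relative to
hip width. Tests assert that re-measured defects agree with assigned
labels.

The dataset generator emulates inter-subject variation: each simulated
subject draws body proportions (global scale 0.85–1.15 with per-segment
variation), camera framing offsets, and per-repetition depth and tempo
around class means. Its defaults *are* the separation experiment: 100
correct repetitions (95 ± 5° peak flexion) versus 100 shallow ones
(45 ± 5°), 1 px jitter — values chosen once as a clearly separated but
noise-bearing two-class task (a parallel squat is ~90–100° of knee
flexion; below ~70° is unambiguously shallow; 1 px is typical estimator
jitter at 720p-range framing). Splits are subject-wise (60/20/20,
stratified by class) so no subject's repetitions leak across partitions.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: pose-estimator error is neither Gaussian nor
independent across joints and frames (it is heavy-tailed, with identity
swaps and correlated drifts); real form defects co-occur and vary within
a repetition; clothing, lighting and camera tilt shift landmarks
systematically; and real correct/incorrect labels come from expert
consensus, not a threshold on one kinematic quantity. The synthetic
separation experiment validates that the pipeline, network and training
machinery are wired correctly — near-perfect accuracy on it says nothing
about accuracy on video data, and the ablation harness asserts structure
(both variants train and report), not the relative ranking of variants.

## Feedback and session scoring

The softmax score of the correct class is thresholded at a configurable
cutoff (default 0.5); a score exactly at the threshold counts **good** —
the boundary had to land somewhere and inclusivity favors the trainee. A
session of repetitions (default 10) reports `n_good` of `n_total`; a
repetition that cannot be preprocessed or is too short to classify counts
as bad with a warning, so a session score always exists. The screening
convention — fewer than 3 goods out of 10 identifies a novice — is the
semantics the session report is built around. Verdicts are monotone in
the score and `n_good` is non-increasing in the threshold; both are
property-tested.

## Numerical choices and degenerate inputs

* Gaussian kernel truncation at ⌈4σ⌉ with renormalization keeps the
  kernel mass at exactly 1 (constants are preserved bit-for-bit).
  Boundary reflection uses the edge-repeating convention with period 2n,
  so sequences shorter than the kernel radius still smooth correctly.
* A reference frame with coincident mid-hip and neck (zero torso) is a
  degenerate pose and errors; a joint never observed anywhere errors as
  data quality rather than being invented.
* The `(0, 0, 0)` keypoint triple and confidence 0 are treated as the
  same missing-joint marker on input.
* Checkpoints store weights column-major at full precision with their
  dimensions, plus the channel-order sidecar; loading refuses a mismatched
  channel order. Keypoint JSON is written with 17 significant digits so a
  write/read round-trip is bit-identical.
* All stochastic steps (simulation, initialization, shuffling, dropout)
  run under locally scoped seeds that do not disturb the caller's RNG
  state; identical seeds give bit-identical datasets and training runs.

## Problem sizes

The experiment scripts and acceptance checks run at sizes chosen to make
the statistical point while staying desk-scale: 200 repetitions (10
subjects per class, ~60 frames each) for the separation experiment, three
independent training seeds for the full model, one seed per ablation
variant, and 10-repetition sessions for the feedback rule. At these sizes
the full pipeline — simulation, preprocessing, training of all three
variants, evaluation and session scoring — completes in well under a
minute on a single CPU core.

## Known limitations

* The classifier judges a whole repetition; it does not localize *which*
  body part is at fault.
* The pipeline assumes a single, frontal, roughly level camera and one
  person (person index 0); multi-person scenes and oblique views are out
  of scope.
* 2D frontal projection is blind to some sagittal information: forward
  lean is observable only through torso foreshortening, which vanishes
  for small lean angles.
* Real-data performance claims require real labeled video; everything
  quantitative here is established on the synthetic task.
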