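---
title: "Automated gaze coding and looking-while-listening analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated gaze coding and looking-while-listening analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazecoder)
```

## The problem

In looking-while-listening (LWL) experiments an infant views two
side-by-side images while hearing speech, and the dependent measure is
which image the child fixates, frame by frame, in a webcam video recorded
at 30 fps. Manual frame-by-frame coding is accurate but extremely
labor-intensive. `gazecoder` implements an automated coder: every frame is
classified as **left**, **right** (screen side, from the child's
perspective) or **away**, the resulting label timeline is cleaned up with
physical-plausibility constraints, agreement with human coders is
quantified, and the standard LWL trial analysis is run downstream. A
synthetic-session simulator with known ground truth makes the whole
pipeline trainable and testable without any real infant video.

## The classifier

### Windowed data points

Human coders judge a frame by scanning its temporal neighborhood, and the
~200 ms saccade latency of infants means the evidence for a gaze shift is
spread over several frames. The classifier therefore never sees a single
frame: a rolling 10-frame window is slid along the video with stride 1,
and from each window the five *alternating* frames (offsets 0, 2, 4, 6, 8)
are selected. Their face crops are stacked into one data point
$V \in \mathbb{R}^{5 \times 75 \times 75 \times 3}$, labeled with the gaze
state of the middle (third) selected frame, i.e., window offset 4. A
sequence of $N \ge 10$ frames yields exactly $N - 9$ data points.

The "every odd element" of a 10-frame window is ambiguous between 1-based
positions $\{1,3,5,7,9\}$ and 0-based offsets; we fix 0-based offsets
$\{0,2,4,6,8\}$, which makes the labeled third-of-five frame the offset-4
frame. The choice is isolated in one constant, and nothing downstream
depends on it beyond consistency.

Faces are located by a pluggable detector (synthetic frames carry their
ground-truth box; for real video any external face extractor can be
plugged in, with a hook for filtering out a parent's face — the largest
box is used by default), cropped, and resized to the fixed
75 × 75 × 3 input resolution. Crops are normalized channelwise with the
mean and standard deviation of the *training* dataset; these statistics
travel with the trained weights, since inference must reproduce them
exactly. An $\varepsilon = 10^{-6}$ guards constant channels.

### Architecture

The network is a stack of convolutional blocks — 3 × 3 kernels, stride 1,
no padding, ReLU, then 2 × 2 max-pooling after each block — followed by
one ReLU dense layer and a softmax over the classes, emitting
$U \in [0,1]^{3}$ (or $[0,1]^2$ for the binary left/right variant), the
probability that the central frame is left, right or away. Kernel size,
stride, padding and pooling are fixed; the per-block filter counts and the
dense width are configuration. The default (32, 64, 128, 128 filters,
dense 256) is sized for real video corpora. The desk-scale experiments in
this package use (8, 16) filters with a 32-unit dense layer: the synthetic
task is low-dimensional (the pupil offset is the only class signal), and
the smaller stack trains in minutes on one CPU while leaving the
contract — multi-frame input, independent per-window softmax output —
identical.

The forward pass and backpropagation are implemented in
Rcpp/RcppArmadillo (im2col convolution lowered to GEMM). Gradients are
verified against central finite differences in the test suite at
$10^{-6}$ step size.

### Training

Training follows the schedule of the original system: mini-batches of 16
data points, Adam with initial learning rate $10^{-5}$, learning rate
halved when the validation loss fails to improve for 3 consecutive epochs,
early stop after 5 stagnant epochs, "improvement" meaning a decrease
greater than $10^{-4}$. The loss is categorical cross-entropy with class
weights 1 : 0.66 : 0.66 (away : left : right): away is rarer in coded
corpora and noisier to label, so its misclassification costs more. The
weights from the best validation epoch are restored at the end.

Two augmentations are applied per training data point, both of which
mirror inference-time conditions:

* **blackout** — one of the five crops, chosen uniformly, is replaced by
  the all-zero "black image", the same sentinel the inference path uses
  when the face detector fails on a non-central frame;
* **brightness** — one multiplicative factor, uniform in [0.7, 1.3], is
  applied to all five crops identically before normalization, with
  clipping to the valid pixel range. The range is a package choice (the
  original work states the augmentation but no range).

The default $10^{-5}$ learning rate is tuned to large real corpora; the
synthetic demonstrations raise it to $10^{-3}$, which converges in a
handful of epochs on the separable synthetic task. Both are plain
configuration fields.

### Inference and missing faces

At inference each complete window is classified independently. If the
face detector fails on the window's *central* frame the frame is labeled
away outright with probability vector $(1, 0, 0)$ — an undetectable face
almost always means the child is not looking at the screen. Failures on
the other four frames substitute the black image and the prediction
proceeds. Frames too close to the sequence edges to center a window (the
first 4 and last 5) are labeled away and flagged `edge = TRUE`, so every
frame carries a label for downstream analysis; analyses in this package
place critical windows away from trial edges, so the edge policy never
touches an analyzed frame. Ties in the argmax are broken in the fixed
class order away < left < right.

## Physical-plausibility post-processing

At 30 fps an infant cannot be fixating left in one frame and right in the
next; manual-coding software refuses such annotations. Because windows
are classified independently, nothing stops the raw network output from
containing such flips. `enforce_constraints()` applies a single
left-to-right scan: if the corrected label at $t-1$ is a side and the raw
label at $t$ is the opposite side, the label at $t$ becomes away. This
preserves both fixations and the shift's timing, alters only frames
participating in an illegal pair (and only to away), and is idempotent.
The test suite checks legality exhaustively over all $3^8$ length-8
sequences.

Only the left↔right rule is mandatory. An optional minimum-fixation
smoother (`smooth_min_run()`) is provided but off by default everywhere:
it is a plausible further constraint, not part of the core contract.
Probabilistic sequence decoding (HMM/Viterbi) is deliberately out of
scope — the correction is meant to be a transparent, local rule.

## Agreement evaluation

Frame-level agreement between an automated timeline and a human reference
is summarized by the support-weighted F1: per-class
$F1 = 2PR/(P+R)$, averaged with weights equal to reference class support,
over frames the human marked valid. Classes absent from the reference are
excluded from the weighting; a class that is predicted but never occurs
contributes $F1 = 0$ with zero weight. Per-video scores are reported as
average and (min–max) across videos, plus a pooled confusion matrix (rows
= reference) and its row-normalized form. A two-class mode restricts
scoring to frames whose reference is left or right, for comparison with a
binary left/right classifier; away predictions on those frames count
against recall. Support weighting is assumed for "weighted" F1 — the
standard meaning.

## The LWL trial analysis

* **Critical window.** Accuracy is computed over frames whose
  onset-relative timestamp $(k - \mathrm{onset}) \cdot 1000/\mathrm{fps}$
  ms lies in $[367, 2000]$, both ends inclusive — at 30 fps, onsets
  offsets 12–60, exactly 49 frames. Inclusive bounds with timestamps
  $k \cdot (100/3)$ ms are the unique convention that reproduces the
  49-frame count.
* **Trial exclusion.** A trial is dropped if the child is away at the
  window's first frame, or away for more than 15 *consecutive* frames
  inside the window (a run touching the window edge counts only its
  in-window length). "At the beginning" is operationalized as the single
  first frame — the source analysis does not define a span. Frames a
  coder marked invalid are treated as away for the exclusion rules and
  excluded from the accuracy ratio (switchable to dropping them
  entirely).
* **Accuracy.** For usable trials,
  $\mathrm{acc} = n_\mathrm{target} / (n_\mathrm{target} +
  n_\mathrm{distracter})$; away frames never enter the ratio.
* **Participant inclusion.** A participant needs at least two usable
  trials in each of the four design cells (noun frequency high/low ×
  sentence frame typical/atypical).
* **Statistics.** Trial accuracies are averaged within participant ×
  cell, then across participants. Each cell is tested against chance
  (0.5) with a two-sided one-sample t test — two-sided is conservative
  for an "above chance" claim; cells with zero variance are flagged, not
  errored. The 2 × 2 fully-within-subjects ANOVA decomposes sums of
  squares per effect with its own participant-by-effect error term:
  $F = MS_\mathrm{effect}/MS_\mathrm{effect \times subject}$ on
  $(1, n-1)$ df, with partial eta squared
  $\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$.
  The decomposition is hand-written (it is part of the package's
  contract) and verified in the tests against `aov()` with error strata
  as an independent oracle, and against the paired-t identity
  $F = t^2$ for 1-df within effects.

## The synthetic-session simulator

The simulator exists to give the pipeline a fully annotated, controlled
stand-in for real video. It has two halves.

**Gaze dynamics.** Ground truth is a semi-Markov process over
left/right/away with explicit dwell times. Side fixations dwell at least
`min_dwell_frames` (default 6 frames = 200 ms at 30 fps, the infant
saccade-latency bound) plus a geometric tail (shifted geometric: simple,
with a directly controlled mean — default mean 9 frames ≈ 300 ms).
Away bouts have geometric dwell with mean 8 frames and occur before a
fixation with probability `p_away = 0.25`; opposite-side fixations with
no away bout between them are separated by exactly one away frame, so the
ground truth itself obeys the same transition rule manual-coding software
enforces (the source material constrains only the *output*; applying it
to truth mirrors human annotation conventions — a convention, not a
claim). Each fixation lands on the trial's target side with probability
`side_bias`; during a trial's critical window the bias *is* the planted
condition accuracy, which is what makes condition effects plantable.
Sequences are generated per trial with an away boundary frame at segment
ends, so trials concatenate legally and the window's first frame starts a
freshly sampled state.

Undetectable ("missing") faces are sampled only within away bouts
(per-frame probability 0.05): a face the detector loses has essentially
always turned from the screen, and this keeps the truth's away label for
missing frames consistent with the side-run dwell invariant. Missing
frames render as faceless background and are the away class in truth.

**Renderer.** Frames are a parametric cartoon face: elliptical head, two
sclera disks, pupil disks whose horizontal offset (±4 px) encodes
left/right and which drop and center for away, plus nuisance factors —
position jitter (±4 px), multiplicative brightness (uniform in
[0.7, 1.3]), Gaussian pixel noise (sd 0.03 in [0, 1] units), and a
~75–80 px usable face, the scale of a webcam-recorded infant face. All
random draws happen before any label-dependent geometry, so frames for
different labels under one seed share their randomness exactly — left and
right renders differ only by the mirrored pupil offset. The renderer is
deliberately *not* photorealistic: it controls exactly what signal exists
(the pupils) and what nuisance exists (brightness, noise, jitter,
missingness). Consequently, passing tests show the pipeline's machinery —
windowing, training loop, missing-face rules, post-processing,
statistics — works end to end; they do not show that a small CNN solves
real infant video, which also contains pose change, motion blur,
occlusion, parent faces and detector noise that the simulator does not
model.

**Study design.** A study is `n_participants` sessions of 32 trials
(8 per cell of the 2 × 2 design, target side balanced within cell, order
randomized). Default planted accuracies are 0.70/0.70 for high-frequency
nouns and 0.60/0.60 for low — a present noun main effect, an absent frame
effect and no interaction, the qualitative pattern the downstream
analysis should recover; their grand mean 0.65 matches the accuracy level
typical of such experiments. Trials are 86 frames with noun onset at
frame 15 (the window then sits at in-trial frames 27–75, clear of the
per-trial edge frames). All seeds derive deterministically from one study
seed, so studies are bitwise reproducible.

## Problem sizes and numerical choices

The package's own experiments (test suite and acceptance script) use:
~2,000 training + 300 validation data points for the classifier, a
(8, 16)/dense-32 architecture, learning rate $10^{-3}$, ≤ 12 epochs;
held-out evaluation on 600 fresh data points; a noise-free control
(600/100 data points, ≤ 8 epochs) where the class signal is exact;
significance-pattern checks over replicated 30-participant ground-truth
studies; and a classifier-annotated study of 12–15 participants with
66-frame trials (onset at 0, window at frames 12–60). These sizes were
chosen so every experiment runs in minutes on a single CPU while keeping
the statistical checks several standard errors wide of their thresholds.

Numerical details fixed by the implementation: probabilities are clamped
at $10^{-12}$ inside the cross-entropy; normalization guards standard
deviations at $10^{-6}$; softmax subtracts the per-sample maximum;
max-pooling drops a trailing odd row/column; argmax ties break
away < left < right; the Monte-Carlo calibration checks average over
replicates because per-sequence target fractions carry fixation-level
correlation (frames within a fixation are not independent draws).

## Known limitations

* The renderer's simplicity means classifier scores on synthetic data are
  upper bounds, far above what any method reaches on real video.
* The away class is identifiable in synthetic frames (centered/lowered
  pupils or no face); in real video away/side confusion dominates coder
  disagreement, so real-data class weights and error structure will
  differ.
* No face detector ships with the package; real-video use requires
  plugging one in (`detect_face(frame, detector = ...)`).
* The post-processor implements only the left↔right rule; further
  constraints (minimum fixation durations) exist in some manual-coding
  pipelines and are available only as the optional smoother.
* Reaction-time and growth-curve analyses of looking are out of scope;
  the trial analysis is the window-accuracy ANOVA described above.
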