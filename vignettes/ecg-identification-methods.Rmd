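---
title: "ECG biometric identification: models, preprocessing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG biometric identification: models, preprocessing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Every person's electrocardiogram carries a stable, individual signature: the
relative amplitudes, widths and timings of the P wave, the QRS complex and
the T wave vary across people far more than they vary across one person's
beats. `ecgid` implements an identification pipeline that exploits this: a
single-channel ECG recording is cleaned, cut into equal-length windows, and
classified to a subject identity by a recurrent neural network built from
the LSTM gate equations up. The package is self-contained — a seeded
synthetic generator produces multi-subject cohorts with exact ground truth,
so every stage (including end-to-end classification) is testable without
access to clinical databases.

## Preprocessing

`preprocess_record()` applies three stages in a fixed order:

1. **Derivative filter** — first difference `y[n] = x[n] - x[n-1]` (a
   central difference is selectable). This kills baseline wander (any
   slowly-varying offset differentiates to almost zero) and emphasises the
   steep QRS slopes that carry most of the identity signal.
2. **Moving-average filter** — centered running mean over an odd number of
   samples, shrinking at the record edges so length is preserved.
3. **Amplitude normalization** —
   `y[n] = 2 (x[n] - median(x)) / (max(x) - min(x))`, computed over the
   *whole record* before any segmentation, so windows cut later share one
   amplitude frame. The median maps to 0 and the output span is exactly 2;
   the map is invariant to positive affine transforms of the input, which
   removes acquisition-gain differences between records.

**Moving-average span.** The default is 25 ms. This was a genuinely open
choice, and an instructive one: a span comparable to the QRS duration
(~100-150 ms, a common smoothing scale for raw ECG) is catastrophic *after*
differentiation — the moving mean of a first difference telescopes to
`(x[n+k] - x[n-k-1]) / w`, so a narrow R deflection of height `a` survives
only as `a / w` while white noise shrinks only as `1/sqrt(w)`. At `w = 55`
(150 ms at 360 Hz) the QRS all but disappears into the noise floor and
R-peak recovery fails; at `w = 9` (25 ms) the QRS is preserved and the
detector recovers peaks essentially perfectly at 10 dB SNR. The span is a
config knob (`preprocess_config(ma_window_s = ...)`) for users who
disagree.

Degenerate inputs error early and explicitly: records shorter than two
samples cannot be differentiated, a flat record cannot be normalized (zero
range), and a moving-average window longer than the record is rejected.

## Segmentation

Two modes produce the classifier's fixed-length inputs:

* **Fixed window** (`segment_fixed()`): consecutive non-overlapping windows
  of `window_samples`; the trailing remainder is dropped rather than
  padded — padding would invent data and distort the late-fusion average.
  288 samples at 128 Hz (2.25 s) and 444 samples at 360 Hz (1.23 s) are the
  canonical sizes for the two MIT-BIH databases.
* **R-peak grouped** (`segment_rpeak_grouped()`): a `beat_window_samples`
  window is trimmed around each detected R peak — one third before the
  peak, two thirds after, so both the P and the T wave fall inside a
  444-sample window at 360 Hz — and runs of `group_n` consecutive beats are
  concatenated. Groups never overlap, so a stratified train/test split can
  never place the same signal stretch on both sides. Beats whose window
  would run off the record, and leftover beats that do not fill a group,
  are discarded.

**R-peak detection** (`detect_rpeaks()`) is a means to segmentation, not a
contribution, and its contract is recovery of known ground truth. The chain
mirrors the classic energy-based recipe, adapted to run *after* the
preprocessing above (whose derivative stage is already half of that
recipe): square the signal, integrate over a 150 ms moving window,
threshold at a configurable fraction (default 0.3) of the local rolling
maximum of that energy, and refine each supra-threshold region to an R
position. Two details matter:

* The threshold tracks the *rolling maximum* (~3 s) of the integrated
  energy rather than a running median. The median sits at an unstable
  point — beat energy occupies a large, heart-rate-dependent fraction of
  any window, so a median multiple either swallows whole records into one
  region or misses low-amplitude beats. A fraction of the local per-beat
  energy ceiling separates QRS humps from T-wave humps (an order of
  magnitude weaker) across amplitude drift.
* In the derivative-filtered signal the R wave is biphasic: a positive lobe
  peaking just before the apex, a negative lobe just after. The apex is
  estimated as the midpoint of the two lobe extrema. (The descending
  zero-crossing between the lobes marks the same point but proved fragile
  under noise.)

Candidates closer than the refractory interval are deduplicated, keeping
the larger-energy peak. The refractory default of 200 ms encodes the
clinical ceiling of 300 beats per minute, and the configuration refuses
smaller values.

## The classifier

One LSTM cell follows the standard gate equations: input, output and forget
gates are logistic-sigmoid functions of affine maps of the current input
and previous hidden state; the modulation gate uses tanh by default
(sigmoid selectable); the internal state updates as
`c_t = f_t * c_{t-1} + g_t * i_t` and the hidden state as
`h_t = tanh(c_t) * o_t`. The forget-gate bias is initialized at 1 so early
training retains state; input and projection matrices use uniform Glorot
fan-based initialization and the recurrent blocks are orthogonal per gate,
all under a seed.

Six registry architectures are exposed (`drnn_arch(1:6)`): unidirectional
stacks of depth 1-3 that classify from the **last** time step's projected
score, and bidirectional stacks of depth 1-3 with **sum-rule late fusion**:
each layer runs a forward and a backward track, deeper layers consume the
per-step concatenation of both tracks, the output projection maps each
top-layer step to a class-score vector (equivalently, the sum of projected
forward and backward scores), and the window-level score is the arithmetic
mean over steps, `Y = (1/T) sum_t y_t`. A softmax (computed with
max-subtraction, so large scores cannot overflow) turns `Y` into class
probabilities **after** fusion, and prediction takes the argmax with ties
broken toward the lowest class index.

ECG samples are fed one scalar per time step (`input_dim = 1`); a
three-beat group of 444-sample beats is thus a 1332-step sequence.

Two implementations coexist deliberately. The exported
`lstm_cell_step()` / `run_layer()` / `forward_pass()` / `late_fusion()` /
`classify()` functions are plain R and define the model semantics; the
training loop and `predict()` call an RcppArmadillo kernel that processes
whole batches. The test suite pins the kernel to the R reference to 1e-12
on every architecture, pins the R reference to an independent scalar-loop
transcription of the gate equations to 1e-10, and checks the analytic
gradient of the kernel against central finite differences — so speed never
drifts away from the specification.

## Training

`drnn()` minimizes the mean cross-entropy of the softmaxed fused scores
with Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) at learning rate
0.001 over shuffled, seeded mini-batches; labels are one-hot encoded
internally. Defaults mirror the reference configuration (cross-entropy,
Adam, lr 0.001, batch 100 — with 1000 the fixed-window variant); epoch
count was unstated upstream, so the package defaults to 50 with plateau
early stopping. With cohorts of only ~100 windows a batch of 100
degenerates to full-batch gradient descent (one update per epoch), so
small-cohort experiments in this package use batch 16.

Three stabilisers address the long-sequence regime (back-propagation
through 1300+ steps), all standard practice and all configurable in
`train_config()`:

* **Gradient-norm clipping** (default 5) bounds rare exploding-gradient
  steps.
* **Reduce-on-plateau decay** halves the learning rate after 3 epochs
  without improvement.
* **Spike backtracking**: if an epoch's loss exceeds 1.25x the best seen,
  the optimizer has jumped out of its basin (a failure mode we observed
  reproducibly around convergence on 1332-step inputs); the fit restores
  the best weights, resets the Adam moments, halves the rate and resumes.
  The returned model always carries the best-loss weights.
* **Restart on stall** (`restarts`, off by default): a small fraction of
  initializations settle into a basin that never sorts all classes (the
  loss plateaus near half the uniform-softmax value with several classes
  never predicted, on data a plain centroid classifier separates
  perfectly). When the final best loss stays above
  `restart_frac * log(C)`, the fit restarts from a derived seed — the same
  remedy `nstart` provides for k-means — and keeps the attempt with the
  lowest training loss; an optional early check (`stall_epoch`,
  `stall_loss`) abandons attempts still stuck at the plateau. Recurrent
  weight blocks are initialized orthogonally (per gate), which makes such
  stalls rarer in the first place.

The training kernel runs in single precision by default — the standard
precision for recurrent-network training, worth ~2x in time on one core —
while prediction and the reference path always run in double. Training is
bit-reproducible for a fixed seed, single-threaded BLAS and a given
precision choice.

## Evaluation

`eval_metrics()` computes, from one-vs-rest confusion counts per class:
per-class precision and recall; overall precision/recall as their
unweighted (macro) means; overall accuracy; and the support-weighted F1,
`sum_c 2 (n_c / N) P_c R_c / (P_c + R_c)`. A class with no predicted (or no
actual) positives contributes 0 to the affected mean, with a warning,
rather than dividing by zero — balanced synthetic cohorts never hit this,
but degraded models do.

Overall accuracy is defined as the proportion of correctly predicted
labels, `sum_c tp_c / N`. Lifting the binary formula
`(TP + TN) / (TP + TN + FP + FN)` to multi-class by summing one-vs-rest
`tn_c` alongside the other counts would instead give
`1 - 2 * errors / (N * C)` — a quantity that exceeds the proportion correct
whenever `C > 2` and is not what accuracy tables in this literature report.
The two coincide for two classes and for perfect prediction; the package
reports the proportion-correct form and exposes the full per-class counts
(including `tn_c`) in `confusion_stats()`.

`split_dataset()` splits windows 80/20 per class, either by seeded
stratified sampling (default) or chronologically (`method = "temporal"`),
since windows cut from one recording are autocorrelated and a practitioner
may prefer a time-disjoint test set. Both sides always retain at least one
window of every class.

## The synthetic generator

`generate_cohort()` emulates exactly the properties the pipeline depends
on, with exact ground truth:

* **Per-subject stable morphology**: each beat is a sum of five Gaussian
  bumps (P, Q, R, S, T) whose amplitudes, widths and within-cycle phases
  are drawn once per subject from documented uniform ranges (e.g. R
  amplitude U(0.9, 1.6) vs T amplitude U(0.2, 0.45); see
  `ecgid:::wave_param_ranges()`). The ranges are wide enough that
  between-subject shape differences dominate within-subject variation —
  verified by the model-free `nearest_centroid_check()`, which must
  separate a noise-free cohort perfectly before any network is trained.
* **Inter-beat variability**: RR intervals are Gaussian around
  `60 / mean_hr_bpm` (mean heart rate drawn from U(55, 85) bpm, SD 2 bpm by
  default), clamped at the 0.2 s clinical floor so synthetic data never
  violates the segmentation refractory assumption.
* **Baseline wander** (0.25 Hz sinusoid, respiratory range) and **white
  Gaussian noise**; `noise_sd_for_snr()` converts a target SNR in dB into a
  noise SD against the clean rendering.

What it does **not** emulate — and therefore what passing tests do not
establish about real recordings: pathological rhythms and ectopy, electrode
motion artefacts, QT/heart-rate coupling, multi-channel structure, and
realistic 1/f noise. The generator is a synthetic stand-in that makes the
pipeline's contracts testable, not a claim of physiological fidelity;
results on it bound software correctness, not clinical performance.

## Training grouped windows: the two-stage ensemble recipe

Fitting a three-layer bidirectional stack directly on 1332-step grouped
windows from ~100 training examples is a fragile non-convex problem: single
runs spend tens of epochs on a loss plateau near `log(C)`, and a
substantial fraction of initializations settle into basins that never sort
all classes. Rather than fight this with ever-longer single runs, the
package's grouped-window studies use `drnn_fit_grouped()`:

1. **Beat-level pre-training.** The training groups are un-concatenated
   with `split_group_windows()` into their component beat windows —
   `group_n` times the examples at `1/group_n` of the
   back-propagation-through-time depth. Because the group-level late-fusion
   score is the average of per-step scores, beat-level cross-entropy
   optimises the same per-step discriminability as group-level training;
   the shorter, better-conditioned problem converges reliably in tens of
   epochs at the reference learning rate.
2. **Group-level fine-tuning.** Each fit is then fine-tuned for a few
   epochs on the actual grouped windows, warm-started, so the objective
   ends exactly where evaluation happens (the hidden state crossing beat
   boundaries is seen in training).
3. **Deep ensembling.** Steps 1-2 are repeated from a few independent
   initialization seeds and the resulting models' class probabilities are
   averaged. Members whose final training loss marks them as stalled
   (above `0.45 log(C)`) are dropped — a decision made on training data
   only. Averaging independently initialized fits cancels member-level
   generalization noise; on the shipped studies it is the difference
   between occasional 0.8-0.9 accuracies and consistent 1.0.

The train/test split happens **before** un-concatenation, so no signal
stretch ever appears on both sides.

## Problem sizes in the shipped checks

The test suite and the acceptance script run a scaled-down version of the
identification study: 6 subjects, 60 s per record at 360 Hz, noise at
~10 dB SNR, R-peak-grouped segmentation with 3 beats per window (1332-step
inputs), architecture 6 (three bidirectional layers, 32 hidden units per
direction) fitted with the two-stage two-member ensemble recipe above
(batch 16, up to 50 pre-training epochs and 25 fine-tuning epochs per
member), repeated over 3 cohort seeds. This trains in a few minutes per
seed on one core and reaches held-out overall accuracy at or near 1.0; the
full-scale configurations (128-250 hidden units, 18-47 subjects,
multi-hour recordings) are expressible with the same functions for users
with the hardware and data.

## Known limitations

* The WFDB reader supports the two dialects the MIT-BIH databases use
  (format 212 and format 16, single interleaved signal file); exotic
  formats, multi-segment records and annotation files are out of scope.
* Model containers are R's native RDS serialization (bit-exact round
  trips); records interchange as WFDB header/signal pairs.
* `keep_prob` applies inverted dropout to the top-layer representation
  only; the reference configuration ("dropout 1") disables it, and no
  claim is made about regularisation benefits elsewhere in the stack.
* Training windows must all share one length within a fit; scoring is
  length-agnostic (the recurrent stack and late fusion accept any window
  length).
* Small-cohort recurrent fits remain a non-convex optimisation: on a
  minority of synthetic cohorts every ensemble member converges to a
  mediocre basin (around 0.7 nats of training loss) whose held-out
  accuracy trails a plain window-centroid classifier on the same split.
  Restarts, longer schedules and extra members mitigate but do not
  eliminate this; the loss trace and the member-loss report make such runs
  easy to recognise.
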