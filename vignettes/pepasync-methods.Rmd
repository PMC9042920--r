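---
title: "Asynchronous decoding of perturbation-evoked potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronous decoding of perturbation-evoked potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pepasync` implements a complete simulated-online pipeline for detecting and
classifying perturbation-evoked potentials (PEPs) in continuous EEG: a
synthetic cockpit-EEG generator, a causal preprocessing chain, a two-stage
hierarchical decoder (PEP-vs-rest detection followed by 4-class
direction/angle classification), an asynchronous sliding-window engine, and
channel-level statistics. This vignette describes the underlying models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The experimental model

The simulator emulates an oddball tilt paradigm: a seated subject is tilted
left or right by a robotic arm. Frequent small *standard* movements (1.5
degrees, slow) are interleaved with rare, sudden *target* perturbations (5 or
10 degrees, left or right). A session has 6 blocks of 40 perturbations — 10
repetitions of each (direction, angle) condition in randomized order, with at
most 2 successive identical conditions — separated by 6–10 standards, giving
inter-perturbation intervals (ISI) of 9–15 s. Perturbations hold the tilted
position for 2 s and return slowly.

`generate_schedule()` draws each ISI uniformly from [9, 15] s and then draws
the number of standards in the gap uniformly from {6, ..., m} where m (at
most 10) is the largest count of non-overlapping 0.8 s standard movements
that physically fits between the end of one perturbation's
ramp–hold–return footprint and the next onset. The joint law of (ISI,
standard count) is not fully determined by the design ranges; coupling the
count to the drawn ISI is the package's choice that keeps both marginal
ranges exact.

Movement kinematics use constant-acceleration (trapezoidal) angular
profiles, discretized so the double integral lands exactly on the target
angle (no drift). The accelerometer measures the tangential acceleration of
a point 0.25 m from the tilt axis plus white sensor noise (0.05 m/s² per
axis). Ramp times (0.2 s for perturbations, 0.8 s out-and-back for
standards, 1 s return) are free parameters of the simulation; they were
chosen so that perturbations exceed, and standards stay well below, the
onset-detection threshold — which is all that matters downstream.

## The synthetic EEG

Each perturbation plants a deterministic PEP template into ongoing
background noise at the true onset:

* **N1**: frontocentral negativity, peak −8 µV at 100 ms (Gaussian bump,
  σ = 30 ms), *identical across all four conditions*.
* **P2**: positivity, +5 µV at 160 ms, spatially lateralized toward the
  hemisphere of the perturbation direction; the right-perturbation map is
  the exact mirror of the left one.
* **Late responses**: a central component inside 0.50–0.63 s whose
  amplitude and duration depend on the angle (−2 µV, σ = 40 ms for 5°;
  +4 µV, σ = 60 ms for 10°, the larger perturbation lasting longer), and
  frontocentral components at ~0.49 s and ~0.9 s whose sign depends on the
  direction (±2.5 µV).

Component scalp maps are spherical Gaussians (σ = 45 mm) projected to the
average reference (zero mean over the montage, renormalized to unit peak):
physical scalp fields of dipolar sources have a return path, and
all-positive maps would otherwise be attenuated by the common-average
reference downstream. Standard movements evoke no response by default
(`standard_amp` exposes a scaled response for sensitivity analyses).

Background noise is a sum of 32 pink-noise sources with random smooth head
maps, an occipital 10 Hz rhythm (3 µV, slowly amplitude-modulated), and
1 µV white sensor noise, scaled to a mean per-channel RMS of 10 µV. The
pink sources follow a 1/f² power spectrum from a 0.05 Hz floor, modelling a
DC-coupled amplifier whose raw RMS is dominated by slow electrode drift —
the very reason the analysis chain high-passes at 1 Hz. After the 1–28 Hz
chain the in-band background is a few microvolts per channel, which places
single-trial detectability in the range implied by the decoding performance
the paradigm is known to support. What the generator does **not** emulate:
eye blinks and saccades, muscle artifacts, vestibular or EMG components,
inter-subject topography variability, and non-stationary drifts of the
sources themselves. Passing tests therefore demonstrate correctness of the
pipeline's machinery and its statistical behavior under a known ground
truth — not performance on real recordings.

The 63-channel montage follows the extended 10-10/10-5 layout on a
spherical head (radius 87.5 mm), built by great-circle interpolation
between midline and outer-ring electrodes.

## Preprocessing

The causal chain (`fit_preprocessor()` / `preprocess_block()`) follows, in
order: 50 Hz notch (constrained biquad, Q = 35), causal order-4 Butterworth
band-pass [1, 28] Hz, decimation to 64 Hz with a causal order-8 anti-alias
low-pass at 25.6 Hz, bad-channel detection, common average reference over
good channels, inverse-distance interpolation of bad channels, and HEAR
artifact correction. All filters are second-order-section cascades with
explicit state, so chunked streaming and whole-record processing are
bit-compatible; this is asserted by tests.

* **Bad channels**: a channel is bad when its maximum absolute correlation
  with its spatial neighbors (within 40 mm, 3–8 nearest) is below 0.75.
  The maximum makes the rule robust to one bad neighbor.
* **Onset detection**: the accelerometer magnitude is high-passed at
  0.5 Hz; onsets are rising-edge crossings of `median + 10·MAD` with a 5 s
  minimum separation. A pure multiple-of-MAD threshold sits below the
  magnitude's own median and would fire continuously; the
  location-plus-scale rule is the standard robust alternative.
* **Epochs**: [−0.06, 1] s at 64 Hz is realized as 4 + 64 = 68 samples
  (1.0625 s, one sample more than the 1.06 s online window); rest epochs
  use the same geometry 448 samples (7 s) earlier, i.e. [−7.06, −6] s.
* **Rejection** (offline only): amplitude ±150 µV; whole-epoch joint
  log-probability beyond 4 SD; per-channel kurtosis beyond 4 SD after a
  `log(excess + 3)` variance-stabilizing transform. The raw 68-sample
  kurtosis estimator is right-skewed enough that a naive per-channel 4 SD
  rule over 63 channels would reject over 20% of perfectly clean epochs;
  after stabilization the clean false-positive rate is a few percent.
  The online entry point exposes no rejection stage.
* **HEAR**: per-channel running variance (exponential smoothing, τ =
  0.25 s) is compared with calibration SDs; channels with variance-ratio
  scores between θ_low = 2 and θ_high = 5 are progressively blended toward
  an inverse-distance neighbor estimate; flagged neighbors are excluded,
  and if none remain the sample passes through with a warning. Fully
  causal.

## The hierarchical decoder

**Stage 1 (PEP vs rest)** uses bilinear common spatial patterns (BCSP).
Classical CSP maximizes the variance ratio between classes through the
generalized eigenproblem `C1 w = λ (C1 + C2) w`. The bilinear variant
learns paired spatial filters `W` (channels × k_s) and temporal filters `V`
(samples × k_t) by alternating two such eigenproblems: given `V`, the
spatial problem on class-mean covariances of `XV`; given `W`, the temporal
problem on `(W'X)'(W'X)`. The alternation starts from `V = I`, tracks the
sum of `max(λ, 1−λ)` over the selected spatial filters, and stops when the
objective change falls below 1e−6 (or 10 iterations; a decrease is treated
as convergence). Filters are taken in pairs from both ends of the
spectrum; covariances are shrunk toward scaled identity (1e−4 · trace/dim).
Whether the original bilinear formulation optimizes one joint objective or
two decoupled ones is ambiguous; the alternating scheme implemented here is
an interpretation and is documented as such. Features are the covariance
diagonals `diag(W'XVV'X'W)` and `diag(V'X'WW'XV)`; both blocks share the
same total energy, which is asserted as an algebraic identity. An RBF-SVM
on z-scored features provides the detection probability through a
Platt-style sigmoid fitted on out-of-fold decision values (5 folds), which
keeps probabilities reproducible and strictly inside (0, 1).

**Stage 2 (direction/angle)** uses the amplitudes of all 63 channels at all
68 samples (4284 features), ranked by Fisher score — between-class over
within-class scatter with maximum-likelihood class variances; zero-scatter
features score 0 and zero-within-variance features get an `Inf` sentinel —
of which the top `k` (default 200) enter a z-normalizer and a one-vs-one
RBF-SVM.

Filter counts, `k`, and SVM hyper-parameters can all be selected by the
shared protocol: stratified 10×10 repeated cross-validation, refitting the
entire chain inside each training fold. The package defaults (k_s = 6,
k_t = 4, k = 200, C = 10, γ = 1/features) were fixed from experiments on
synthetic subjects and keep routine runs fast; the grids from the selection
functions reproduce the full search.

## Asynchronous operation

`stream_classify()` slides a 68-sample window one sample (15.625 ms) at a
time over online-preprocessed 64 Hz data. The BCSP features of all window
positions are computed by causal convolution of the spatially projected
signal with the reversed temporal filters — algebraically identical to
per-window matrix products, and tested to be so. A detection is emitted
when the calibrated probability reaches the threshold outside a 2 s
refractory period; its time is the time of the window's last sample
(causal semantics).

The operating point comes from the tuning block (block 5): 500 evenly
spaced thresholds in (0, 1) are scored by the F1 of their matched
detections (ties go to the higher threshold, i.e. fewer false positives),
and the mean *time lag* between matched detections and true onsets
calibrates the epoch realignment for stage 2 — at inference, the 4-class
epoch is anchored at `detection time − mean lag`. The multiclass model
itself is trained on ground-truth-aligned calibration epochs; applying the
lag at inference only (rather than shifting the training epochs) is the
reading implemented here, and the training-side alternative can be
composed from the exported pieces.

Scoring on the validation block (block 6): a detection is a true positive
if it falls within (0, 2] s after an unmatched onset (earliest onset
first; this greedy rule attains the maximum-matching TP count, verified
against an exhaustive oracle); detections more than 2 s after every onset
count as false positives. Binary accuracy is 100·TP/(TP+FN) (false
positives affect only precision/F1, because the negative class is
unbounded), `F1 = 2TP/(2TP+FP+FN)`, and 4-class metrics (accuracy, macro
one-vs-rest F1, confusion matrices with angle and direction marginals) are
computed over the correctly detected trials only.

Block partitions are fixed — blocks 1–4 calibration, block 5 tuning,
block 6 validation — and enforced: the tuner refuses calibration blocks,
the validator refuses calibration and tuning blocks, and configurations
with overlapping partitions are rejected.

## Statistics

`signed_r2()` maps the point-biserial correlation between amplitude and
class membership to `sign(r)·r²` per channel and sample. The interval
tests compare per-trial mean amplitudes — over samples whose post-onset
time lies inside the closed window, so [0.50, 0.63] s at 64 Hz covers
post-onset samples 32–40 — with a one-sided Wilcoxon rank-sum test per
channel and window, Bonferroni-corrected with family size 252 (63 channels
× 4 windows). The design specifies one-sided testing without fixing the
direction; the direction per window is taken from the sign of the
grand-average difference at the channel where that difference is largest
in magnitude. (Pooling the difference over channels, the more obvious
rule, is degenerate here: average-referenced data have a channel-pooled
mean difference of essentially zero, so its sign is noise.) Default windows: angle contrast
[0.08, 0.15], [0.15, 0.20], [0.32, 0.50] and [0.50, 0.63] s; direction
contrast [0.08, 0.15], [0.15, 0.17], [0.42, 0.56] and [0.80, 1.00] s. Only
the late windows are pinned by the underlying design; the early windows
are reconstructions and should be treated as configurable defaults, not as
reference values.

Grand averages are subject-weighted when a subject grouping is supplied
(per-subject means first, then across subjects), which differs from
trial-pooling under unbalanced designs; a regression test pins the
subject-weighted choice.

## Numerical and interface choices

* Butterworth and notch designs are computed analytically (prototype
  poles, band transform, bilinear transform) and realized as second-order
  sections; an independent transfer-function design is used as a test
  oracle. Band edges sit at −3 dB by construction.
* The native container round-trips losslessly; EDF+ export quantizes to
  16 bits over a stated symmetric physical range and stores ground-truth
  markers as EDF+ annotations (round trip exact to one quantization step
  and one sample).
* All stochastic steps (schedules, noise, folds) are seeded; two runs of
  `run_pipeline()` with the same configuration produce byte-identical
  reports.
* Degenerate inputs have documented behavior: constant features normalize
  to 0 with a warning, zero-TP tuning raises an error (the lag cannot be
  calibrated), all-flagged HEAR neighborhoods pass through with a warning,
  and empty schedules yield empty recordings.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at reduced but non-trivial
scale, chosen as the package's own test-scale convention: the end-to-end
recovery suite simulates 3 subjects with 6 blocks of 24 perturbations
(6 per condition) at default SNR, plus the same subjects at 10× noise for
the degradation check (3 seeds); the family-wise-error suite uses 200
null simulations of 12-trial groups; the planted-effect suite uses 100
trials per condition over 5 seeds. The full study scale (40 perturbations
per block) runs unchanged through the same functions.

## Known limitations

* The simulator's PEP is deterministic per condition; real PEPs vary in
  latency and amplitude from trial to trial, which would widen the
  detection-lag distribution and lower multiclass accuracy.
* Ocular/muscle artifact models (and hence ICA-style removal) are out of
  scope; the rejection and HEAR stages are tested against synthetic pops,
  drifts and bursts only.
* The EDF+ implementation covers the subset of the format the simulator
  emits (EDF+C, one annotation channel); it is not a general EDF reader.
* Scalp topographies are exported as per-channel value tables; rendering
  is left to external tools.
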