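---
title: "Methods: gait phases, oscillator phase estimation and angle-phase fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait phases, oscillator phase estimation and angle-phase fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitfuse` is a processing stack for lower-limb exoskeleton research on
pathological walking.  This vignette is the package's account of the
models it implements, the parameters that matter, and the design
decisions taken where the design was genuinely open.  Code chunks are
illustrative and not evaluated during build; the same computations run in
the test suite and in `scripts/acceptance.R`.

## The four-phase / four-stage scheme

Exoskeleton assistance is only active around swing, so each leg is
divided into four phases rather than a fine clinical subdivision: stance
(code 0), pre-swing (1, heel-off to toe-off), swing (2) and swing
termination (3, heel-strike to foot-flat).  Walking couples the legs
rigidly — pre-swing on one side coincides with swing termination on the
other, swing with stance — so only four bilateral stages exist, written
`Gait 20, 31, 02, 13` (left digit, right digit) and advancing cyclically
`20 → 31 → 02 → 13 → 20`.  `contralateral_phase()`, `stage_of()` and
`next_stage()` encode the scheme; illegal pairs are rejected rather than
silently repaired, which is what makes the per-frame legality property
testable.

### The trend labeler

Manual annotation is replaced by a deterministic labeler driven by the
two sagittal ankle angles.  The key observation is that all four stage
transitions of a stride coincide with an extremum of one side's sagittal
angle: the left apex (heel-strike) starts Gait 31, the right valley
(right toe-off) starts Gait 02, the right apex starts Gait 13, the left
valley (left toe-off) starts Gait 20.  The labeler therefore arms on a
sustained rise or fall of a smoothed slope (`rise_threshold`,
`fall_threshold`, in degrees/frame, both 0.2 by default), requires an
excursion of at least `stance_band` degrees (default 5°) so that noise on
the flat stance plateau cannot arm it, and emits the raw-series extremum
that ends each armed trend.  A stage state machine consumes the events in
cyclic order; events that do not match the expected next stage are
discarded.  Consequences:

* every emitted frame pair is legal by construction;
* on noiseless recordings (where simulator segment boundaries sit on
  sample frames, see below) recovery of the ground truth is exact for
  normal, foot-drop and staggering gait, and the collapsed stage sequence
  always follows the cyclic order;
* scissor gait saturates against its clip band, so its apex/valley
  plateaus are genuinely ambiguous — tied extrema resolve to the middle
  tied frame, and agreement drops to roughly 0.90, mirroring the clinical
  observation that the scissor stance/pre-swing boundary is indistinct.

Degenerate inputs follow fixed rules: constant series produce `(0, 2)`
throughout; a confirmed rise with no completed apex labels that side as
swinging from the start of the series.  Transition frames always belong
to the newer stage.  The pre-swing onset has no clean kinematic marker in
ankle angles alone; tying it to the contralateral apex (one event, two
simultaneous phase changes) is this package's resolution of that gap.

## The synthetic gait generator

No public recordings of the three pathological gaits exist, so the
simulator is a first-class module and defines the study conditions.  Each
cycle is anchored at left toe-off.  Sagittal ankle waveforms are
piecewise cubic smoothstep segments through four control values — toe-off
minimum, heel-strike maximum, stance plateau — giving a flat stance, a
pre-swing descent, a swing ascent and a termination descent with zero
slope at every junction.  Segment boundaries are quantized to integer
frames so that ground-truth labels, waveform extrema and the continuous
phase (0–100%, resetting exactly at left toe-off frames) coincide on the
sample grid; this is what makes exact self-consistency between simulator
and labeler a meaningful test rather than an approximation.

Pattern deformations, with their defaults:

* **normal** — control values 40/90/65°, phase proportions
  10/40/10/40% (pre-swing/swing/termination/stance), cycle duration
  `mean_cycle` (1 s) with Gaussian jitter of CV `cycle_jitter_cv` (0.05).
* **scissor** — a 48/83/78° template hard-clipped into
  `ankle_range_clip = c(50, 80)`°, bilaterally symmetric; clipping both
  narrows the range and blurs the stance/pre-swing boundary.
* **foot-drop** — unilateral, affected side left.  Affected stance is
  drawn uniformly within ±25 ms of `affected_stance_ms` (175 ms, i.e.
  150–200 ms); the healthy stance — which equals the affected swing —
  uniformly within ±175 ms of `healthy_stance_ms` (525 ms, i.e.
  350–700 ms); the two transition stages take 10% of the cycle each.  The
  affected-side maximum is lowered to 72° against a 65° plateau,
  suppressing the heel-strike peak.
* **staggering** — swing ascent ranges forced to
  `ascend_range_affected = 19.60`° (left) and
  `ascend_range_healthy = 29.64`° (right), with a raised default timing
  jitter (CV 0.12) for the irregular step rhythm.

Yaw and roll ankle channels are low-amplitude cycle-locked sinusoids;
thigh and shank sagittal targets are smooth two-harmonic curves of the
leg's own cycle position.  Gaussian noise (`noise_sd`, default 0.5°) is
added to every channel *after* labels and phase are derived, so ground
truth is exact at any noise level.  The sampling rate is configurable
(default 100 Hz — millisecond-scale stance statistics require tens of Hz
or more).  What the generator does **not** emulate: forward dynamics,
ground reaction forces, EMG, soft-tissue artifacts, sensor drift or any
specific patient; passing tests show the algorithms work under the
stated kinematic conditions, not that they transfer to clinical data.

## Cycle normalization

Cycles of unequal length are aligned to the longest cycle `m` by linear
interpolation on the grid `x_i = i/(m−1)·(n−1)`; when a query point
coincides with a knot the knot value is returned exactly, so endpoints
are preserved and `m = n` is the identity.  Linearity is appropriate
because within a phase the sagittal angle changes approximately linearly;
spline alternatives are deliberately out of scope.  Ensemble statistics
use the sample standard deviation (n−1): the twenty-cycle summaries the
statistics are meant for are samples, not populations.

## Adaptive-frequency-oscillator phase estimation

The sagittal left ankle angle is reconstructed by `n_osc` harmonics
(default 3) with a shared fundamental,

\[
\hat\theta = \sum_{i=1}^{N} \alpha_i \sin\varphi_i + \alpha_0,\qquad
e = \theta - \hat\theta,
\]

\[
\dot\varphi_i = i\,\omega + \vartheta_\varphi\, e \cos\varphi_i, \quad
\dot\omega = \vartheta_\omega\, e \cos\varphi_1, \quad
\dot\alpha_i = \eta\, e \sin\varphi_i, \quad
\dot\alpha_0 = \eta\, e,
\]

integrated by explicit Euler at the sample rate (a refined-step
comparison test bounds the discretization error).  The printed form of
the adaptation law is structurally ambiguous about whether the coupling
is per-oscillator or normalized by the amplitude sum, and whether the
frequency adapts per oscillator; this implementation uses per-oscillator
coupling through `cos(φᵢ)`, a single shared fundamental adapted through
the first oscillator, and an optional `1/Σ|αᵢ|` normalization flag
(default off).  The continuous phase is `mod(φ₁, 2π)/2π·100%` — applied
to the phase itself, not its derivative, since a rate cannot represent a
cycle-normalized position.

Gains are not reported anywhere authoritative; the defaults
(`gain_phase = 0.4`, `gain_freq = 0.4`, `gain_amp = 0.3`) were fixed once
by the frequency-recovery calibration the package ships as an acceptance
check — on `10·sin(2πft) + 60` at 0.5, 1 and 2 Hz for 30 s at 100 Hz,
starting 20% below the true frequency, the learned `ω/2π` lands within
0.1% of `f`.  The fundamental is clamped at `omega_floor` (10⁻³ rad/s)
with a one-shot warning.  Initialization: `ω` from the first toe-off
interval when events are supplied, `α₁` from the input SD, `α₀` from the
input mean.

### The toe-off reset

Continuous estimation drifts relative to the anchoring event, so the
estimate is forced to 0% at every detected left toe-off.  Two mechanisms
are implemented.  The default, `reset_mode = "anchor"`, re-anchors the
*emitted* phase (`φ(t) = mod(φ₁ − φ₁^{reset}, 2π)`), leaving the
oscillator dynamics untouched.  The alternative, `reset_mode = "zero"`,
zeroes the pool phases themselves.  The zeroing variant forces the
sin-only amplitude basis to re-fit the waveform's phase offset every
stride: measured on noiseless simulations its frequency estimate decays
and the mean absolute circular phase error grows to ~30 percentage
points, against 2–6 points for anchoring.  Anchoring is therefore the
default; resets never touch amplitudes, offset or frequency.  Cadence
transients (standing starts, abrupt speed changes) remain a known
failure mode of this estimator class and are out of scope.

## Angle-phase fusion and the predictors

Seven consecutive frames of the six ankle channels plus the estimated
phase form a 7×7 window (`build_samples()`); the target is the four
sagittal thigh/shank angles `round(horizon · fs)` frames past the window
(half-away-from-zero rounding; horizons 0, 0.5, 1, 5 s by convention,
any value accepted).  Dropping the phase column gives the 7×6 control
input for the fusion ablation.  Splits are random by sample at 6:2:2
with five seeded repeats by default, matching the printed protocol of
repeated random splits; because overlapping windows leak information
across a random split, a `block = TRUE` option instead splits along time
and drops training windows that touch held-out anchor or target frames.
The default remains the protocol-faithful random split.

The predictor family (all trained with MSE, Adam, learning rate 0.001,
batch 32, 100 epochs, seeded init and shuffling):

* `cnn_lstm` — same-padded 1-D convolution over the time axis (64
  filters, kernel 3, ReLU) → LSTM (64 units) → dense(4) on the last
  hidden state;
* `cnn_only` / `lstm_only` — the hybrid minus one layer group, every
  remaining hyperparameter identical (`predictor_layers()` exposes the
  contract);
* `cnn_lstm76` — the hybrid on the phase-free 7×6 input.

The exact layer sizes are artifact constants (the originating
architecture diagrams are not enumerable from text); they are
configurable and documented in `predictor_spec()`.  Inputs and targets
are standardized on training statistics inside the model (predictions
return in degrees).  This is a conditioning choice for the small
networks and short schedules used here — with raw degree-scale targets,
Adam's bounded per-step movement cannot reach a ~60° output offset
within 100 epochs — and it applies identically to every variant, so
ablation comparisons are unaffected.

The stage classifier takes the instantaneous six ankle angles (not
windows), convolving across the channel axis: conv(16) → pool →
conv(32) → pool → dense(32) → softmax(4), stride-1 same-padded pooling
so every layer preserves length, cross-entropy, 100 epochs at 0.001.
"Iterations" in the source description are read as epochs, consistent
with the predictor's stated schedule.  The comparison baseline is an
RBF-kernel support-vector classifier with C = 1 (via `e1071`); its
decision values are reported and ties resolve to the lowest class index.

The layer engine itself (conv1d/maxpool/LSTM/dense forward and backward,
Adam) is written in plain R matrix algebra — the networks are tiny and
no deep-learning runtime is part of the package's dependency footprint —
and its gradients are validated against central finite differences at
10⁻⁵ relative tolerance in the test suite.

## Evaluation and statistics

RMSE and PCC follow their textbook definitions and are tested against
independent brute-force implementations at 10⁻¹² tolerance.  PCC is
undefined for zero-variance series and errors distinctly from a length
mismatch.  Confusion matrices are 4×4 with overall and per-class
accuracy; on simulated data misclassifications concentrate almost
entirely in stages adjacent in cycle order, which the tests assert as a
diagnostic.  Repeat-level PCC values are compared with Kruskal–Wallis;
when the omnibus is significant, Dunn's pairwise z tests (pooled ranks,
tie correction) are adjusted with Holm's method — the adjustment is a
package default, named in every report, since the original analysis does
not state one.  Timing is captured per evaluation but treated as a
hardware-dependent diagnostic: it is excluded from serialized artifacts
so that identical experiments produce byte-identical outputs.

## Determinism and problem sizes

A single global seed fans out to per-stage seeds through a fixed affine
map (`seed · 7919 + offset, mod 2147483`), so `run_pipeline()` reruns are
byte-identical and each stage is independently reproducible.  The test
suite and acceptance script run on recordings of 6–30 s at 100 Hz
(roughly 600–3500 frames, 20–200 cycles as the check requires) with the
full 100-epoch schedules for the headline classifier and fusion
experiments and reduced epochs where a property does not depend on the
schedule; these sizes are the package's chosen experimental conditions
and are stated in the relevant tests.

## Known limitations

* Simulated kinematics only; no claim of clinical fidelity transfers
  from these tests to patient data.
* The phase estimator assumes quasi-periodic input with detectable
  toe-off events; cadence transients degrade it.
* The scissor labeler is intentionally imperfect near its saturated
  boundaries (the boundary genuinely is indistinct).
* Random-by-sample splits leak temporally overlapping windows between
  train and test; the protocol-faithful default keeps them, the
  `block = TRUE` option removes them, and reported in-package accuracies
  should be read accordingly.
* The serialized feature container is CSV/JSON, chosen over a binary
  scientific container to keep artifacts text-based and diff-friendly.
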