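# gaitfuse

Pathological gait simulation, continuous phase estimation and
angle-phase-fused lower-limb angle prediction for exoskeleton control
research.

## The problem

Lower-limb exoskeletons need two things from their sensing stack: *where
in the gait cycle the user is* (so assistance is applied in the right
phase) and *where the limbs will be shortly* (so the controller can act
before, not after, the movement).  Both are hard for pathological
walking — scissor, foot-drop and staggering gaits are asymmetric,
aperiodic and noisy, and clinical recordings of them are scarce.

`gaitfuse` implements a complete, testable processing stack for this
setting:

1. **Synthetic gait generator** — bilateral ankle/thigh/shank Euler-angle
   recordings for normal, scissor, foot-drop and staggering patterns with
   exact ground-truth phase labels.  The pathological deformations follow
   the clinically reported characteristics: scissor sagittal ankle range
   confined to 50–80° with a blurred stance/pre-swing boundary; foot-drop
   with a 150–200 ms affected-side stance against a 350–700 ms
   healthy-side stance and no heel-strike peak; staggering with a 19.60°
   affected-side swing ascent against 29.64° on the healthy side.
2. **Four-phase / four-stage labeling** — each leg is in stance (0),
   pre-swing (1), swing (2) or swing termination (3); bilateral coupling
   admits only the stage pairs Gait 20, 31, 02, 13, which advance
   cyclically.  A trend/extremum labeler recovers the stages from the two
   sagittal ankle channels alone.
3. **Cycle normalization** — variable-length cycles are aligned to the
   longest cycle by linear interpolation,
   `x_i = i/(m−1)·(n−1)`, `y_i = b_j + (b_{j+1}−b_j)(x_i−x_j)/(x_{j+1}−x_j)`,
   and summarized as mean ± SD over a 0–100% cycle axis.
4. **Adaptive frequency oscillator (AFO)** — a pool of N harmonics
   reconstructs the sagittal ankle angle as
   `θ̂ = Σᵢ αᵢ sin(φᵢ) + α₀`, with the tracking error driving phase,
   frequency, amplitude and offset adaptation.  The continuous gait phase
   `φ(t) = mod(φ₁, 2π)/2π · 100%` is forced to 0 at every detected left
   toe-off, anchoring the estimate to the event that defines 0%.
5. **Angle-phase fusion and prediction** — seven consecutive frames of the
   six ankle channels plus the estimated phase form a 7×7 input window; a
   compact CNN–LSTM hybrid predicts the four sagittal thigh/shank angles
   at horizons of 0, 0.5, 1 or 5 s.  Convolution-only, recurrence-only and
   phase-free (7×6) ablations share the same hyperparameters.
6. **Evaluation** — RMSE and Pearson correlation against held-out truth,
   4×4 stage confusion matrices, and Kruskal–Wallis + Dunn (Holm)
   comparison of repeat-level model performance.

The networks are deliberately tiny and are implemented directly in R
(explicit forward/backward passes, Adam); gradient correctness is pinned
by finite-difference tests, and all training is seed-reproducible.

## Worked example

```r
library(gaitfuse)

rec <- simulate_recording(sim_config("foot_drop", duration = 30, seed = 1))
sag <- sagittal_channels(rec)
lab <- label_phases(sag$left, sag$right)
mean(lab$phase_left == rec$phase_left &
     lab$phase_right == rec$phase_right)
#> [1] 0.9663333

phi <- afo_run(sag$left, rec$sample_rate, detect_toe_off(lab$phase_left))
phi$final_state$omega / (2 * pi)        # learned cadence, Hz
#> [1] 1.041199
circular_phase_error(phi$phi[600:3000], rec$true_phase[600:3000])
#> [1] 3.393898

fs  <- build_samples(rec, phi, horizon = 0.5)      # 7x7 windows, 4 targets
sp  <- split_samples(fs, split_spec(repeats = 1, seed = 11))[[1]]
fit <- train_predictor(predictor_spec("cnn_lstm"),
                       fusion_subset(fs, sp$train),
                       fusion_subset(fs, sp$val), seed = 101)
te  <- fusion_subset(fs, sp$test)
evaluate_predictor(fit, te, gait = "foot_drop", horizon = 0.5)
#> <eval_report> cnn_lstm | gait=foot_drop horizon=0.5 rep=NA | RMSE 3.826 deg, PCC 0.9410
```

The numbers read as follows: the trend labeler agrees with the simulator's
ground truth on ~96% of frames at the default noise level; the oscillator
locks close to the true ~1.15 Hz foot-drop cadence and tracks the
continuous phase to ~3.4 percentage points mean absolute circular error;
and the angle-phase-fused hybrid predicts the four limb angles half a
second ahead to ~3.8° RMSE with a mean per-channel Pearson correlation of ~0.94.  Dropping
the phase column (`predictor_spec("cnn_lstm76")`, `phase = FALSE` in
`fusion_subset()`) degrades the same experiment to ~4.7° RMSE — the
fusion benefit the package is named after.

A full simulate → label → estimate → fuse → train → evaluate run, with
every intermediate written to disk, is one call:

```r
run_pipeline(pipeline_config(gait = "foot_drop", seed = 1), "artifacts/")
```

A thin command-line wrapper over the same functions ships in
`inst/cli/gaitfuse` (subcommands `simulate`, `label`, `normalize`, `afo`,
`features`, `run-all`).

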