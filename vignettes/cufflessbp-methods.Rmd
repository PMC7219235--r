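---
title: "Cuff-less blood pressure estimation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuff-less blood pressure estimation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Continuous, cuff-less blood-pressure (BP) monitoring estimates systolic and
diastolic pressure (SBP/DBP, mmHg) from non-invasive cardiovascular
waveforms: the electrocardiogram (ECG), the finger photoplethysmogram (PPG)
and the seat-sensor ballistocardiogram (BCG). The physiological anchor is
pulse transit time (PTT) — the interval from the ECG R peak to a distal
pulse fiducial — which is negatively correlated with BP; the R-J interval
(RJI) from the ECG R peak to the BCG J wave carries related timing
information.

`cufflessbp` implements two estimators over synchronized ECG/PPG/BCG
recordings with beat-to-beat reference BP:

* an end-to-end deep network: a VGG-style 1-D CNN encoder, a bidirectional
  GRU, feed-forward attention pooling and an affine head emitting
  (SBP, DBP) from raw 5-s windows;
* a classical comparator: per-cycle interval features (RRI, PTT, RJI) from
  rule-based fiducial detection, regressed onto SBP/DBP by ordinary least
  squares.

Because no public recording with this channel combination exists, the
package ships a synthetic generator whose ground truth makes every stage
testable.

## The synthetic world

`synth_config()` states the emulated conditions; these defaults are the
package's test world and are not tuned per test:

* 1000 Hz sampling, the acquisition rate the preprocessing assumes;
* heart rate 70 bpm with 2 bpm beat-to-beat jitter;
* PTT 250 ms baseline, modulated ±30 ms over a 30 s slow cycle
  (an autonomic-like drift that gives BP its within-recording dynamics);
* RJI 180 ms ± 5 ms, truncated to [112, 248] ms so the planted J wave
  always lies inside the 110–250 ms search window;
* linear negative coupling SBP = 165 − 0.2·PTT(ms), DBP = 95 − 0.1·PTT(ms),
  landing mean SBP/DBP at 115/70 mmHg — the resting means the estimators
  are validated around;
* additive baseline wander (0.3 Hz), power-line (60 Hz) and white noise on
  every channel.

Morphology is a documented package choice, because only timing and coupling
are load-bearing: QRS complexes are Gaussian mixtures, the PPG pulse is
`(u/τ)² exp(−u/τ)` with τ = 0.12 s, and the J wave is a Ricker (Mexican
hat) lobe of width 20 ms. The PPG template puts the maximum first
derivative exactly `(2 − √2)·τ ≈ 70.3 ms` after pulse onset
(`ppg_dpeak_offset()`), so PTT measured at the derivative peak equals the
planted PTT plus a known constant.

Two deliberate generator properties:

* per-beat BP noise (`bp_noise_sd`) is a knob *separate* from waveform
  noise and defaults to 0 mmHg: the planted coupling is exact by default
  and measurement noise enters through the waveforms. This keeps
  `cor(PTT, SBP) = −1` exactly in noise-free runs and lets the
  MLR-consistency check (`RMSE → σ`) set its own σ;
* ground truth is drawn from an RNG stream independent of the noise
  stream, so raising noise amplitudes never changes the truth.

What the generator does **not** emulate: Windkessel-style hemodynamics,
motion artifacts beyond additive noise, respiratory modulation, or
pathological morphologies. A green test therefore establishes that the
pipeline recovers planted timing/coupling under stationary additive noise —
not clinical accuracy on real patients, which requires real cohorts.

## Preprocessing

Each channel is band-passed with a zero-phase 2nd-order Butterworth
(forward–backward, so fiducial timings are not skewed by group delay; the
magnitude response is |H|²): ECG 0.5–35 Hz, BCG 4–15 Hz, PPG 0.5–15 Hz.
The design is a bilinear-transform implementation validated against a
numerically evaluated frequency response (−3 dB at both cutoffs). Edge
transients are handled by odd signal extension whose length adapts to the
slowest filter pole.

The pipeline order is: filter at the native rate → resample the whole
record to 125 Hz (FFT method; the channels are band-limited by then) →
segment. Windows are half-open 5-s spans (625 samples at 125 Hz) advanced
by a configurable stride; the nominal 1 ms shift at 1000 Hz corresponds to
the minimum realizable 8 ms (one-sample) shift after resampling, and the
default `stride_s = 0.008` records that reading. Each window's target is
the beat value in force at its final sample (sample-and-hold interpolation
of the beat series); windows ending before the first annotation are
dropped. Targets outside mean ± 1.96 SD (SBP or DBP, bands from the dataset
passed in) are eliminated; with the cohort statistics 115.04 ± 14.64 mmHg
this band is [86.35, 143.73]. The rule is applied exactly once — it is only
approximately idempotent because the retained subset has new statistics.
Per-window, per-channel standardization (zero mean, unit variance) is on by
default since raw sensor units are arbitrary across channels.

## The network

For a 625 × C window the architecture is:

| stage | output |
|---|---|
| 4 conv blocks of {2,2,3,3} layers (kernel 3, conv→BN→ReLU), channels 64→128→256→512, each ending in maxpool size 3 stride 3 (same padding, ceil lengths) | 625 → 209 → 70 → 24 → 8 |
| Bi-GRU, 64 hidden nodes per direction, states concatenated | 8 × 128 |
| attention: scalar score `tanh(Ws h_i + b)` per step, softmax weights, weighted sum | 128 |
| affine head | 2 (SBP, DBP) |

The GRU cell uses the update/reset/candidate equations with blending
`h_t = (1 − z_t) ⊗ h_{t−1} + z_t ⊗ h̃_t` and a zero initial state. Design
points that were genuinely open:

* biases are included in the gates (standard practice; the published
  equations omit them) with a config switch to disable;
* the attention score maps each 128-vector to one scalar through tanh; the
  head is purely affine (BP is unbounded regression, so no output
  nonlinearity);
* batch-norm placement is conv → BN → ReLU; ε = 1e−3 and running-stat
  momentum 0.99 are the usual framework defaults and are recorded in the
  config. For reduced CPU-scale runs the pipeline uses momentum 0.9: with
  only a handful of minibatches per epoch the running statistics would
  otherwise lag the batch statistics for tens of epochs and validation
  (evaluated in eval mode) would be meaningless early on;
* max pooling pads with −∞ so padded positions never win, which yields the
  ceil-division length chain;
* weights are Glorot-uniform from a recorded seed.

Because no deep-learning framework exists in the target environment (and
the network is the package's core), the forward pass, backpropagation
(including through time) and Adam are implemented in base R matrix code;
the backward pass is validated against numerical gradients and the GRU
against an independent scalar-loop oracle.

## Training protocol

70/10/20 train/validation/test fractions; Adam with learning rate 1e−3 and
the classic per-update inverse-time decay `lr_t = lr/(1 + 1e−4 · t)`; MSE
over the standardized (SBP, DBP) pair; early stopping on validation MSE
with patience 10 inside at most 50 epochs, restoring the best-validation
weights; batch size 512 at full scale. Targets are internally z-scored
from the training split (predictions return in mmHg).

Two open protocol points were resolved as follows. The 70/10/20 split is
chronological and contiguous by default — windows shifted by milliseconds
overlap almost entirely, so random splits would leak the test windows into
training; `split_method = "random"` mirrors the literal reading.
Calibration-based evaluation trains within a subject's own recording
(per-subject reading); the calibration-free regime is leave-one-subject-out
(LOSO): the held-out subject's windows form the test set and the remaining
subjects split 87.5/12.5. On the synthetic cohort with subject-specific BP
intercepts the LOSO error exceeds the calibration error, as it must when
the network cannot observe a new subject's offset.

## The MLR baseline

R peaks come from a Pan-Tompkins chain (derivative, squaring, 150 ms
moving-window integration, adaptive signal/noise thresholds with a 200 ms
refractory period, refinement to the local ECG maximum); every threshold is
relative, so detection is invariant to amplitude scaling. The J peak is the
highest BCG point 110–250 ms after each R; a cycle is invalid when the
window is truncated, the maximum sits on the window boundary (the planted-
outside-window case), or the peak falls below 25% of the median detected
peak. The PPG derivative peak is searched in (r, r + 0.6 s] — wide enough
for physiologic PTT, short enough not to capture the next beat at ≥ 50 bpm
— with an ~11 ms symmetric smoothing of the derivative to stabilize the
argmax under in-band noise. Manual false-positive exclusion is replaced by
these automated plausibility rules. Cycles missing any fiducial are
excluded and the exclusion fraction is reported (denominator: cycles
between consecutive R peaks).

RRI/PTT/RJI (seconds, native-rate timing) feed per-target OLS. On
noise-free cohorts the PTT coefficient recovers the planted slope exactly
(−0.2 mmHg/ms appears as −200 mmHg/s, and the intercept absorbs
slope × `ppg_dpeak_offset()`); with per-beat BP noise σ the residual RMSE
converges to σ.

Two measurement caveats are documented rather than hidden: the 0.5 Hz
high-pass edge slightly reshapes the slow PPG pulse, and at short RR /
long PTT the previous pulse's tail overlaps the rise, each biasing the
derivative fiducial by a few ms. The timing specification
(onset + 70.3 ms) therefore holds exactly on clean, constant-PTT signals;
on modulated or filtered signals the bias is systematic and harmless to
the regression slope.

## Evaluation conventions

* errors and Bland–Altman differences are estimate − reference; limits of
  agreement are mean ± 1.96 SD;
* sample (n−1) standard deviations everywhere;
* the SD quoted beside MAE is the SD of absolute errors; the AAMI SD is
  the SD of signed errors — both are computed and named;
* AAMI: pass iff |mean error| ≤ 5 mmHg and SD ≤ 8 mmHg (inclusive); the
  85-subject sufficiency requirement is a reported flag, not a failure;
* BHS: percentages of |error| within 5/10/15 mmHg, inclusive thresholds,
  best satisfied row of A 60/85/95, B 50/75/90, C 40/65/80, else D;
* attention heat map: with 8 time steps over 625 samples, sections are 81
  samples (648 ms) except the truncated 8th (58 samples, 464 ms); the end
  of section 6 lies 1.112 s and of section 2 lies 3.704 s before the
  target BP at the window end.

## Numerical and engineering choices

* FFT resampling keeps the folded Nyquist bin real; identity when the
  rates match; upsampling is out of scope;
* the outlier band degenerates gracefully at SD = 0 (nothing removed);
* `fit()` aborts on a non-finite loss with the epoch in the message;
* training is deterministic given seeds (weight init, shuffling and the
  generator use separated derived streams, all below 2³¹);
* EDF I/O is unsupported in this build (no EDF library in the
  environment); recordings travel as CSV plus a JSON beat sidecar so
  annotation times survive exactly. Windowed datasets serialize with
  `saveRDS` at run time (no HDF5 binding available);
* the CLI (`inst/cli/cufflessbp.R`) is a thin argument parser over
  exported functions; every subcommand has an identical library call.

## Limitations

Synthetic validation bounds what green tests mean: the network's headline
clinical accuracies on real cohorts are not reproducible here (the
original cohort is private), so the package validates architecture
arithmetic, estimator recovery of planted couplings, protocol semantics
and the standards suite. The reduced-width network used on CPU is the same
code path as the full architecture (scale = 1 reproduces it exactly), but
its absolute errors on the synthetic cohort are not comparable to
published cohort errors.
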