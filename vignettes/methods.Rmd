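---
title: "Generating and evaluating synthetic accelerometer fall data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating synthetic accelerometer fall data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable fall-detection classifiers learn from triaxial accelerometer
recordings, but real falls are rare, hazardous to stage, and ethically
difficult to collect from the elderly population the detectors are meant
to protect. Datasets therefore contain hundreds of activity-of-daily-living
(ADL) recordings for every labeled fall, and classifiers trained on them
have poor recall on the minority class. `fallsynth` addresses this by
*synthesizing* fall windows three ways, *measuring* how faithful the
synthetic data is, and *quantifying* whether it actually improves a
downstream detector — all under leakage-guarded, subject-wise evaluation.

This vignette explains the models, the defaults and why they were chosen,
the numerical decisions, and what the built-in simulator does and does not
establish about real data.

## Data model and windowing

A `trial` is one continuous recording: an L x 3 matrix in m/s^2 with a
sampling rate, subject id, activity label, and optional *fall intervals*
(half-open, 0-based sample index pairs; chosen once and used everywhere
because half-open intervals compose without off-by-one arithmetic).
Classifiers consume fixed `W x 3` windows cut by a sliding window of
`W = 128` samples and hop 10; at ~32 Hz a window spans about four seconds,
long enough to contain an entire fall event. Trailing samples that do not
fill a window are dropped rather than padded, keeping the input shape
fixed.

A window is labeled a fall when at least half of its samples lie inside a
fall interval. The 50% threshold is symmetric (a window is a fall iff it
is mostly fall) and standard in human-activity recognition; it is
configurable via `windowing_spec()`. For this rule to be meaningful the
labeled interval must be commensurate with the window: the simulator
labels from ~0.5 s before the free-fall onset to ~1 s after the impact
(~2.5 s), the way bench datasets annotate fall onset through post-impact.

Splits are by **subject** (70/20/10 of subjects for train/validation/test,
rotated across 5 folds over a seeded subject permutation): windows from one
person are strongly correlated, and window-level splits would leak identity
into the test set. Class balancing (`balance_with_synthetic()`) appends the
*minimum* number of synthetic fall windows that brings the training fall
fraction within tolerance of 50%, never removes real windows, never adds
synthetic non-falls, and is refused anywhere except the training partition.

## Classic augmentations

Three label-preserving transforms generate variations of real fall
windows:

* **Jittering** adds iid Gaussian noise (default sigma 0.3 m/s^2, well
  below impact amplitudes) — robustness to sensor noise.
* **Magnitude warping** multiplies the window by a smooth curve: scaling
  factors ~ N(1, 0.2^2) drawn at 4 equally spaced knots, interpolated by a
  natural cubic spline. One shared curve across axes by default, so the
  orientation ratios between axes are preserved; per-axis curves are
  opt-in.
* **Rotation** applies a uniformly random-axis rotation with angle up to
  30 degrees (Rodrigues formula), emulating a different sensor placement.
  Rotation preserves the per-sample magnitude ||a(t)|| exactly — the
  physically meaningful invariant of re-orientation.

The parameter defaults are conventional IMU-augmentation values; none are
stated by the protocol this package operationalizes, and all are exposed
in `augment_config()`.

## The diffusion generator

The centerpiece is a denoising diffusion probabilistic model (DDPM) over
whole fall trials. The forward process corrupts a trial `x0` with
Gaussian noise over `T = 300` steps under a linear beta schedule; a 1D
U-Net is trained to predict the injected noise (epsilon-prediction, MSE
loss, Adam); ancestral sampling runs the learned reverse chain from pure
noise to a new synthetic trial.

**Variable lengths.** Trials differ in length, so all trials are padded to
`L_new = ceil(L_max / 8) * 8`, each with its own last sample value (not
zeros: a zero tail would fabricate a spurious step edge; the last value
extends the quiescent lying phase naturally). 8 is the halving factor of
the three-resolution U-Net. Original lengths are retained and generated
trials are cropped back to a length drawn from the empirical training
length distribution.

**Denoiser.** Kernel-7 / padding-3 convolutions capture temporal
dependencies at every resolution. Each level stacks two ResNet blocks
(RMSNorm -> SiLU -> conv, with a learned per-channel shift injected from
the diffusion-timestep embedding) and one linear-attention block;
downsampling is space-to-depth plus projection, upsampling
nearest-neighbour plus projection, with channel-concatenating skip
connections (channels 32/64/128). RMSNorm normalizes each position's
channel vector to unit RMS before a learned gain, which keeps activations
scale-stable under the unnormalized, heavy-tailed accelerometer inputs.

Two embeddings condition the denoiser: a sinusoidal embedding of the
*diffusion timestep* (dim 32, passed through a 2-layer MLP and injected
into every ResNet block), and sinusoidal *sequence-position* channels
(8 of them) concatenated to the input. The position channels matter:
convolutions are translation-equivariant, but padded trials are temporally
aligned, so the fall phases (pre-fall ADL, free-fall dip, impact,
quiescence) live at consistent absolute positions that a purely
convolutional network could not address.

**Numerical choices.**

* Residual-branch closing convolutions, attention output projections and
  the final layer are initialized to zero, making the network the identity
  at initialization. Without this, each of the ~16 residual branches adds
  O(1) noise at init, the input's share of the activation decays like
  1/sqrt(depth), and at desk scale the denoiser never escapes the
  zero-prediction plateau.
* The beta schedule runs from 1e-4 to 0.06. The conventional endpoint of
  0.02 is calibrated for T = 1000; at T = 300 it would leave ~5% of the
  signal at the terminal step, violating ancestral sampling's assumption
  that the chain starts from pure noise. 0.06 restores a terminal signal
  fraction of ~1e-4.
* Sampling converts each noise prediction to an implied clean signal,
  clips it to the training data's (standardized) value range, and draws
  from the corresponding posterior. Without this standard stabilizer the
  reverse chain compounds prediction error exponentially.
* Signals enter the model unnormalized, as required for preserving the
  extreme impact kinetics; internally the denoiser standardizes by the
  training set's global per-axis mean/sd and inverts the transform exactly
  on sampling, so the no-normalization contract holds at the I/O boundary.
* Training runs 30 epochs over 64 trials in minibatches of 2 with cosine
  learning-rate decay from 1e-3; one seed governs initialization, batching
  and noise draws, so runs reproduce bit-for-bit. An exponential moving
  average of the weights is available (`ema_decay`) but disabled by
  default: at ~1000 optimizer steps the average lags the live iterate too
  much to help.

These training sizes are desk-scale choices: the whole train/sample cycle
runs in minutes on one CPU core. A practitioner with a GPU-week would
raise T, epochs and channel counts; the configuration surface exposes all
of it.

## Pose-trajectory conversion

The third generator converts 3D joint trajectories (produced by an
external video pose estimator; 17 standard skeleton joints) into virtual
accelerometer streams. The acceleration of a joint with positions `p(f)`
sampled every `dt` seconds (default 1/46 s) is the discrete second
derivative — velocity from position changes, acceleration from velocity
changes — evaluated per axis at interior frames:

    a(f) = (p(f+1) - 2 p(f) + p(f-1)) / dt^2

This central second difference annihilates constant and linear motion
exactly and recovers the acceleration of smooth trajectories to O(dt^2);
on a free-fall parabola it returns 9.81 m/s^2 at every interior frame to
machine-level accuracy (a test asserts this).

Because differentiation amplifies tracking noise quadratically, clips
first pass occlusion QC — rejected when the joint is validly tracked in
fewer than 95% of frames or any invalid run exceeds 3 frames; surviving
interior gaps are linearly interpolated — and are then smoothed by a
5-frame centered moving average. Cropping to the annotated fall frames
(plus a 1.5 s margin) happens *before* QC and smoothing, so quality rules
are enforced on exactly the material that will be differentiated. The
estimator's coordinate scale is assumed meters; a `scale` factor covers
estimators emitting other units, since nothing in the keypoints themselves
reveals the unit.

## The five quality metrics

All five compare a real and a synthetic window set.

* **Context-FID** — a small 1D convolutional autoencoder is trained on the
  *real* windows only; both sets are embedded at its 32-dimensional
  bottleneck and compared by Frechet distance between Gaussian fits,
  `||mu_r - mu_s||^2 + tr(S_r + S_s - 2 (S_r^{1/2} S_s S_r^{1/2})^{1/2})`.
  The embedder is deliberately self-contained (no pretrained weights
  exist for wrist accelerometry); it is returned alongside the score so
  several synthetic sets can be ranked against one real set under one
  embedding. Rank-deficient covariances (fewer windows than dimensions)
  get a small ridge and a warning rather than an error.
* **Discriminative score** — held-out accuracy of a small recurrent
  classifier trained to tell real from synthetic (80/20 split). 0.5 means
  indistinguishable; 1.0 means trivially separable.
* **Predictive score** — train-on-synthetic, test-on-real: a small
  recurrent one-step-ahead forecaster is fitted on the synthetic windows
  and its next-step RMSE is measured on the real windows, in m/s^2.
  Synthetic data that carries the real temporal structure transfers well.
* **JSD** — per axis, all sample values of both sets are pooled,
  histogrammed on the shared min-max range (50 bins), and compared by
  Jensen-Shannon divergence with base-2 logarithms (hence in [0, 1]);
  axes are averaged.
* **KS D-bar** — the two-sample Kolmogorov-Smirnov D statistic (maximum
  ECDF gap) per axis on pooled values, averaged over the three axes, with
  asymptotic p-values per axis. Pooled marginals are the only reading that
  yields a single D per axis.

`distribution_plot()` writes the standard three-panel overlaid histogram
(real vs synthetic values per axis).

The discriminative score is reported as raw accuracy in [0, 1] per its
definition; published tables in this literature occasionally contain
discriminative or JSD values above 1 that no transformation of these
definitions reproduces, and this package does not attempt to match such
values.

## The detector and the utility protocol

The downstream classifier is intentionally simple: an LSTM over the
`128 x 3` window, batch normalization of the final hidden state, a dense
layer as wide as the window with ReLU, and a sigmoid output; binary
cross-entropy, Adam, early stopping on validation loss. Hidden size,
learning rate (1e-3), epochs and the 0.5 decision threshold are
conventional defaults, all in `detector_config()`.

`run_protocol()` is the experiment that answers "does synthetic data
help?": for each of 5 folds it splits windows subject-wise, trains a
baseline on the real training partition, trains a second model on the same
partition balanced toward 50/50 with synthetic fall windows, and evaluates
both on the untouched real test partition, reporting fold-averaged
precision/recall/F1/accuracy. Generated trials are windowed densely
(hop 1 instead of 10) when building the synthetic pool — every generated
trial is a fall throughout, so dense windowing simply extracts more
training material per trial; real data keeps the standard hop. Two leakage guards are hard invariants,
enforced at runtime and asserted in tests: no subject spans partitions,
and no synthetic window ever reaches validation or test.

## The simulator: what it does and does not show

`simulate_corpus()` generates the study conditions every test runs under:
10 subjects x 4 trials at 32 Hz with a 10% fall fraction. ADL trials
(8-20 s) are a randomly tilted gravity projection plus a gait-like
oscillation (~1.5-2.1 Hz, amplitude 2 m/s^2 scaled by a per-subject
multiplier with spread 0.15) plus band-limited noise. Fall trials (~4.2 s)
are ADL prefix -> free-fall dip (magnitude below 3 m/s^2 for 0.35 s, the
near-weightless phase of a fall) -> half-sine impact spike with peak
20-35 m/s^2 along a per-fall-type axis pattern (front/back/left/right,
plus a precessing rotational type) -> quiescent lying on the impacted
side. Fall and ADL trials are separable by peak magnitude at these
defaults, which makes the detector fixture's F1 target attainable by
construction. Trial durations are deliberately short so that diffusion
training, sampling and the 5-fold protocol together run in minutes on one
core; the vignette-stated sizes are the package's reference conditions.

What passing tests on this simulator establish: the algorithms are
implemented correctly, the generators beat trivial baselines on it, the
metrics order corruption levels correctly, and the protocol's leakage
guards hold. What they do not establish: performance on real wearable
data, where falls are not amplitude-separable from vigorous ADLs (sitting
down hard, jumping), sensor placement varies continuously, and
inter-subject variability far exceeds a scalar amplitude multiplier. The
simulator is a test harness, not evidence of field performance.

One known limitation is worth stating plainly: the pooled per-axis value
distribution of simulated falls is close, in sup-CDF distance, to a
Gaussian matched to its first two moments, so the "beat a moment-matched
white-noise surrogate on KS D-bar" check sets an unusually strong bar for
a generator trained from scratch for 30 epochs; the diffusion model's
margin on that single check is thin and seed-dependent, while it wins
clearly on the context-FID, discriminative and JSD axes of the same
comparison.

## Reproducibility

Every stochastic component takes a seed: the simulator, the three
augmentations, diffusion training (one seed for init/batching/noise) and
sampling, both learned quality scores, and the detector. Identical seeds
reproduce results bit-for-bit; tests assert this for each component.
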