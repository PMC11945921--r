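---
title: "Estimating blood glucose from PPG pulse waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood glucose from PPG pulse waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgcaps)
```

## The estimation problem

Photoplethysmography (PPG) measures blood-volume pulsations optically; the
waveform's per-beat morphology — systolic rise, diastolic component, beat
timing — carries physiological information that correlates with blood
glucose level (BGL). `ppgcaps` implements a complete non-invasive BGL
estimation pipeline: segment preprocessing, an eight-family morphological
and spectral feature vector, and a capsule-network regressor trained with a
sparse-filtering objective, evaluated with the glucose-monitoring metric
battery (MAE, MSE, RMSE, MAPE, R², MARD, Bland–Altman agreement).

Clinical PPG-with-reference-glucose corpora are rarely public, so the
package ships a first-class synthetic cohort generator. All experiments in
the package's tests and acceptance script run on generated cohorts; the
generator's defaults define the study conditions and are documented below.

## The synthetic cohort generator

Each subject receives demographics (age 18–85 y, weight 40–120 kg, gender
balanced) and a fasting glucose drawn from a three-component normal mixture
(means 5.2, 7.0 and 9.2 mmol/L with weights 0.5/0.25/0.25, truncated to
[3.2, 14.0]), spanning the normal, prediabetic and diabetic bands. The
non-fasting reading adds a postprandial increment `N(0.9, 0.5)` bounded
below by −0.9 mmol/L. Two segments per subject alternate the fasting and
non-fasting condition, mirroring a paired collection protocol; segments are
1700 samples at 115.2 Hz by default.

A beat is the sum of a systolic Gaussian (SD 0.09 s, peak 0.162 s after
onset) and a diastolic Gaussian (delay 0.30 s, width 1.6× systolic) at
heart-rate spacing, with heart rate per subject from `N(75, 6)` clipped to
[55, 100] bpm. On top: baseline wander (0.1 a.u. sinusoid at 0.12 Hz),
white noise (SD 0.02 a.u.) and powerline interference (0.01 a.u. at
50 Hz). The wander frequency sits in the slow vasomotor band on purpose:
the baseline estimator below is a ~3 s moving average, and the generator's
drift must lie inside the band that filter can remove.

**Glucose coupling.** The regression target must be recoverable, so
glucose is coupled monotonically to morphology through two affine maps
with seeded subject-level jitter:

* systolic amplitude `= 1.5 − 0.08·BGL + N(0, 0.03)` (decreasing),
* diastolic ratio `= 0.2 + 0.02·BGL + N(0, 0.02)` (increasing).

The slope and jitter values were fixed once, by the design requirement
that the measured per-beat amplitude correlate with BGL at `|r| ≥ 0.7` on
a 200-segment cohort. Two properties of the measurement chain motivated
the final slope: the inter-beat valley depth and the local mean subtracted
by baseline removal both scale with the beat period, so heart-rate
variability leaks into the measured systolic rise; with slope −0.08 and
the narrowed heart-rate spread the measured amplitude–BGL correlation is
≈ −0.9. Jitter is a *subject* effect (one draw per subject, shared by both
conditions), which is what a grouped train/test split must respect.

**What the generator does not emulate.** Real PPG exhibits
subject-specific waveform shapes, motion artifacts, sensor coupling drift,
arrhythmias, and — critically — a far weaker and confounded
glucose–morphology relationship. Passing the end-to-end recovery test
therefore shows the pipeline can extract a morphological glucose signal
when one exists; it is not evidence of clinical accuracy on real data.

## Preprocessing

Order: baseline removal, then Savitzky–Golay smoothing
(`preprocess_segment()`).

* `moving_average(x, N)` averages the symmetric window `[i−N, i+N]`
  (`2N+1` points); edges use symmetrically shrunken windows so length and
  phase are preserved. Baseline removal subtracts a wide moving average
  (default half-window `round(1.5·fs)` samples, i.e. a ≈3 s window — several
  beats wide, so the pulse train passes through while drift is removed).
* `savitzky_golay(x, window, polyorder)` performs least-squares polynomial
  smoothing (defaults window 11 ≈ 95 ms, degree 3), which preserves peak
  shape far better than plain averaging. Edge samples are produced by the
  fitted polynomials of the first and last complete windows rather than by
  reflection padding: reflected polynomials are not polynomials, and exact
  reproduction of degree-≤ p polynomials at *every* sample is the property
  the test suite pins down.

Both filters are linear; the suite checks linearity, the brute-force
window-mean oracle, and polynomial reproduction to 1e−9.

## The feature vector

`extract_feature_vector()` assembles 36 values in eight blocks from a
preprocessed segment (default framing: 256-sample frames, hop 128,
256-point FFT — a frame is ≈2.2 s, at least two beats):

1. **AR (5)** — Yule–Walker AR(5) coefficients of the whole segment
   (biased autocovariances, Levinson solve, sign convention
   `Σ c_k γ(l−k) = −γ(l)`), a parametric encoding of the spectral
   envelope. `ar_power_spectrum()` exposes the implied spectrum.
2. **KTE (4)** — mean/variance/IQR/skewness over the per-frame mean
   Teager–Kaiser energy `a(t)² − a(t+1)a(t−1)`, an instantaneous
   energy operator that is exactly `A² sin²(ω)` on sinusoids.
3. **HRS (4)** — the same statistics of the beat-to-beat heart-rate series
   from detected systolic peaks.
4. **HS (4)** — statistics of per-frame spectral entropy (Shannon entropy
   of the normalised power spectrum, natural log; 0 for a pure tone,
   `log L_FFT` for a flat spectrum).
5. **LogEP (7)** — AR(5) coefficients of the per-frame log-energy series
   `log(Σx² + 1e−12)` plus its variance and IQR.
6. **PTT (4)** — statistics of onset-to-onset intervals (within the single
   PPG channel; this is the pulse-period reading of transit time, not the
   ECG-to-PPG definition).
7. **PPI (4)** — statistics of peak-to-peak intervals, the PPG proxy for
   R–R intervals.
8. **PA (4)** — statistics of the per-beat systolic rise
   (peak − preceding onset; offset-invariant on baseline-removed signals;
   a raw-peak mode is available).

The stated block sizes total 36; statistics use the unbiased variance,
linear-interpolation quartiles and adjusted Fisher–Pearson skewness, with
skewness 0 by convention on constant series. Peak detection uses local
maxima with a 180 bpm separation ceiling and a prominence gate at 0.3× the
median prominence; a leading pulse whose onset falls on the first sample
was cut mid-rise by the recording window and is dropped. Blocks whose
inputs are insufficient (e.g. no detectable beats) are zero-imputed and
flagged in `imputed_blocks` rather than failing the segment.

## The capsule network regressor

`build_dscnet()` assembles, for a 1-D segment:

1. convolution (kernel 9, stride 1, default 256 channels) + ReLU;
2. a primary-capsule convolution (kernel 9, stride 2) whose channels are
   reshaped into 8-dimensional capsules and squashed with
   `v = (‖s‖²/(1+‖s‖²))·s/‖s‖`;
3. digit capsules (default 3 × 16-dimensional, one per glucose band as a
   capacity choice) via learned transformation matrices and
   routing-by-agreement (default 3 iterations): coupling logits start at
   zero, are softmax-normalised over output capsules, and accumulate the
   prediction/output agreement;
4. a regression head — flattened digit capsules, optionally concatenated
   with the standardized 36-element feature vector, through
   dense(128) + ReLU + dropout(0.5) + dense(1, linear) — emitting BGL in
   mmol/L.

Design choices worth stating:

* **1-D convolutions.** The input is a waveform; the 9×9 kernels of
  image-capsule practice become kernel-9 1-D convolutions with the same
  channel counts.
* **Position-shared transforms.** The digit-capsule transformation
  matrices are shared across primary-capsule positions within each map
  (a convolutional capsule layer). Per-position matrices on 6 736 primary
  capsules would be computationally prohibitive on a CPU and add millions
  of parameters for 1 700-sample inputs; sharing preserves the squash,
  routing and sparse-filtering mathematics unchanged. With sharing, the
  routed vote sums factor as `s_r = Σ_m W_mr (Σ_p C_pmr u_pm)`, which the
  compiled kernels exploit so the full prediction tensor is never
  materialised.
* **Stop-gradient routing.** The backward pass treats the coupling
  coefficients as constants (no gradient through the routing iterations'
  logit updates), a standard simplification; with one routing iteration
  the coupling is exactly uniform and the implemented gradient is the
  exact gradient, which is how the finite-difference test pins the
  backward pass down.
* **Sparse filtering.** The unsupervised objective is the L1 norm of the
  row- then column-L2-normalised feature matrix — minimal (`= M`, the
  sample count) when each sample activates one feature, maximal
  (`M·√N`) for uniform activation. During training it is applied to the
  digit-capsule activation matrix and its gradient updates only the
  capsule transform weights, in two modes: `joint` (added to every
  supervised step with weight λ, default 1e−3) and `alternating` (one
  unsupervised transform-weight step per `sf_every` supervised steps).
  The standalone `sparse_filtering_loss()`/`sparse_filtering_grad()` pair
  carries the analytic gradient, checked against finite differences.
* **Self-attention.** Scaled dot-product attention over positions with a
  residual connection; optional after the primary-capsule convolution
  (capsule model) or after every block (CNN baseline).
* **CNN baselines.** `build_cnn_baseline()` is the four-block
  conv(3)–pool(2)–dropout stack (filters 32/64/128/256) with the same
  regression head, with and without self-attention, used by
  `run_ablation()`.

Training (`train_model()`) minimises MSE on internally-standardized
targets with Adam (lr 1e−3, batch 16, ≤200 epochs by default), early
stopping on the RMSE of a 15 % validation carve-out (patience 20),
restoring the best weights. Every random element — initialisation at build
time, shuffling, dropout, the carve-out — is seeded, so training is
reproducible on a single CPU thread. A non-finite loss aborts with a
diagnostic rather than continuing. `predict_bgl()` de-standardizes and
clamps to [1, 30] mmol/L with a warning.

## Evaluation

`compute_metrics()` implements MAE, MSE, RMSE, MAPE, R² and MARD. MAPE and
MARD have the same formula for positive references and coincide on every
dataset this package produces; both are reported because both names are
standard in glucose monitoring. R² of a constant-reference set is an
explicit error rather than a silent NaN. `split_train_test()` shuffles and
splits 80:20 *grouped by subject* by default: the two segments of one
subject share the jittered physiology, so a per-segment split would leak.
Glucose categorisation closes the printed band gaps with half-open
midpoint boundaries ([3.9, 6.15), [6.15, 7.85), [7.85, ∞)) so it is total
and monotone, flagging out-of-band values instead of refusing them.
`run_ablation()` trains the baseline and self-attention variants on
identical splits across ≥3 seeds and reports per-seed metrics, mean ± SD
and the relative improvements `100·(base − attn)/base`; means over seeds
are used because single-run differences at this scale are noise-dominated.
`agreement_report()` produces Bland–Altman bias and 1.96·SD limits.

## Problem sizes and numerical choices

The test suite and the acceptance script run a *reduced* configuration —
32 convolution channels, 8 primary maps (6 736 primary capsules on a
1700-sample segment), ≤40 epochs with patience 12 on a 200-subject cohort
— which one CPU core trains in a few minutes per seed; the default
full-size configuration (256 channels, 32 maps) is the same code. Other
numerical conventions: ε = 1e−8 guards in the sparse-filtering
normalisations (all-zero rows/columns pass through), ε = 1e−12 in the
log-energy floor, ties in max-pooling take the earlier position,
`0·log 0 := 0` in the entropy, and seeds fan out from a single global seed
through a fixed integer map so any stage can be replayed independently.

## Known limitations

* The glucose–morphology coupling is synthetic and far stronger than any
  reported physiological effect; held-out R² on generated cohorts says
  nothing about clinical performance.
* The sparse-filtering update is a first-order method on a non-smooth
  objective; its loss can tick upward when supervised steps move the
  shared weights.
* MAPE and MARD are redundant here by construction.
* The routing stop-gradient makes the training gradient approximate
  whenever more than one routing iteration is used.
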