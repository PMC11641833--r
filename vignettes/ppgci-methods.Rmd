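---
title: "Classifying low cardiac-index states from the finger photoplethysmogram"
author: "ppgci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying low cardiac-index states from the finger photoplethysmogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cardiac output (CO) — and its body-surface-normalized form, the cardiac
index (CI, L/min/m²) — is the central marker of hemodynamic adequacy in
major surgery and critical care. The reference measurement, continuous
thermodilution through a pulmonary-artery catheter, is invasive. The
finger photoplethysmogram (PPG), by contrast, is ubiquitous: every pulse
oximeter produces one. `ppgci` implements a screening pipeline that
classifies 60-second PPG windows into **Low** (CI ≤ 2 L/min/m², the
conventional low-cardiac-output-syndrome cutoff, boundary inclusive) and
**NonLow** states, using the waveform morphology of a per-window
ensemble-averaged beat.

The pipeline has six stages, each exposed as ordinary R functions:
simulate or ingest paired PPG/CI records → quality-screen and window →
build a representative beat → extract twenty pulse-wave features →
weight features with the Relief algorithm → train and evaluate a
gradient-boosted decision-tree classifier.

## Windowing and the reference value

PPG is processed in 60-s windows in which consecutive windows share
10 s, i.e. the hop is 50 s; window spans are half-open
`[start, start + 60)` with 0-based starts at 0, 50, 100, … seconds. We
note the alternative reading of "overlapping by 10 s" as a 10-s hop and
reject it: at a 50-s hop, several hours of recording per subject produce
window counts in the few-thousands, the regime this kind of analysis
reports; a 10-s hop would produce five times as many.

The thermodilution monitor updates CI every 60 s and the channel is
recorded at 0.5 Hz, so a window typically contains one or two distinct
CI values. The window's reference is the *last* CI value inside its
span, and the label is `Low` iff that reference is ≤ 2.0 (the threshold
is configurable). Windows without any CI value in their span are
dropped and counted.

Quality screening replaces manual visual inspection with explicit
rules: missing-sample gaps, flat-line runs longer than 2 s, samples
beyond 6 robust standard deviations (1.4826 × MAD) of the record
median, and CI recording gaps all invalidate samples; a window is used
only if every sample in it is valid. These rules are a stand-in for
judgment-based exclusion, not a reproduction of it.

## Signal conditioning

Each window is band-pass filtered (second-order Butterworth sections,
0.1–15 Hz) and then linearly detrended. Two choices deserve comment:

* **Zero-phase filtering.** The filter is applied forward–backward so
  that fiducial *timings* (the foot-to-upstroke interval, the beat
  duration) are not phase-shifted. Plain forward–backward filtering
  leaves large edge transients, so the window mean is removed first and
  the signal is reflection-padded before filtering.
* **Detrending.** "Removing the DC offset" is implemented as removal of
  the per-window least-squares line (mean-only removal is available via
  `detrend_signal(linear = FALSE)`). The result has zero mean to
  numerical precision.

Filtering-then-detrending is approximately idempotent; the residual on
a second pass is dominated by low-frequency energy sitting on the
0.1-Hz high-pass shoulder (e.g. respiratory-scale wander at 0.2 Hz
passes with gain slightly below one, so a second pass removes a little
more of it). The tests bound this at 5 % of the window range over the
window interior.

## The representative beat

Within a window, systolic peaks are detected as local maxima with
topographic prominence ≥ 0.3 × the window's median peak-to-trough
amplitude and a minimum spacing of 0.3 s. The amplitude base is the
median over 2-s blocks of (block max − block min): a robust estimate of
the typical beat amplitude that is not dragged down by noise wiggles
(an earlier variant using the median *candidate prominence* let
dicrotic secondary waves through and doubled the detected heart rate).

Beats are delimited **foot to foot**, the foot being the amplitude
minimum between consecutive peaks, so that the representative beat
starts at the landmark required by the foot-referenced timing feature.
Beats whose length deviates more than 40 % from the median are
excluded; the survivors are linearly time-normalized to the median beat
length and averaged pointwise. Time-normalization prevents heart-rate
variability from smearing the dicrotic notch in the average; the mean
period is retained separately so duration features are not lost.
Windows with fewer than three usable beats are dropped with a logged
reason. First and second derivatives of the representative beat are
central differences scaled by the sample interval.

Averaging `n` beats reduces additive noise by about 1/√n, which the
test suite verifies numerically.

## Fiducial points and the twenty features

On the foot-aligned representative beat we locate: the systolic peak
(global maximum), `a1` (first local maximum of the first derivative
before the peak — the steepest upstroke), `b2` (global minimum of the
second derivative), `c1` (first local maximum of the second derivative
after the peak), and the dicrotic notch (first local minimum after the
peak, falling back, for notch-free beats, to the post-`c1` sample where
the first derivative is closest to zero). Ordering invariants
(foot < a1 < peak < notch ≤ end) are enforced; beats violating them are
dropped with a logged reason.

The twenty features are computed per window with declared conventions
(the published descriptions name the quantities but not the formulas);
the full list is documented in `?compute_features`. Three conventions
matter most:

* `plethPerf` (perfusion-index proxy) is computed on the **raw**
  window — (95th − 5th percentile) / median — because detrending
  destroys the DC level that a perfusion index needs.
* `plethSat` is the mean of the monitor's SpO₂ numeric channel over the
  window. A single-wavelength PPG cannot physically yield saturation,
  so the numeric is treated as an auxiliary input channel.
* The three spectral entropies use a Hann-windowed periodogram with the
  DC bin excluded, normalized by the log of the retained bin count, so
  values lie in [0, 1] (≈0 tonal, ≈1 broadband). The Hann window keeps
  a pure tone's leakage inside a few bins, which is what makes the
  tonal/broadband ordering sharp.

Whether the statistical and spectral features should be computed on the
representative beat or on the whole window is ambiguous in the source
description; this package computes beat-shape statistics
(skewness, kurtosis, peak-to-RMS, FFT mean, derivative entropies and
quantiles, areas) on the representative beat and `plethSpecEntropy` on
the filtered window, and declares these choices rather than inferring
them.

## Relief feature weighting

Relief for a continuous response (RReliefF) rewards predictors that
differ where the response differs and penalizes predictors that differ
where it does not. Per iteration an observation \(x_r\) is drawn and
its \(k\) nearest neighbors \(x_q\) found; three running weights
accumulate:

\[
W_{dy} \mathrel{+}= \Delta y(x_r,x_q)\, d_{qr},\qquad
W_{dj} \mathrel{+}= \Delta j(x_r,x_q)\, d_{qr},\qquad
W_{dy \& dj} \mathrel{+}= \Delta y\, \Delta j\, d_{qr},
\]

and after \(m\) iterations each predictor's weight is

\[
W_j \;=\; \frac{W_{dy\&dj}}{W_{dy}} \;-\; \frac{W_{dj}-W_{dy\&dj}}{m - W_{dy}}.
\]

Quantities the algorithm's verbal description leaves open are fixed as
the standard RReliefF choices and documented: \(\Delta y\) and
\(\Delta j\) are absolute differences scaled by the observed range of
the response/predictor; \(d_{qr}\) are exponentially decaying
rank-distance weights \(\exp(-(\mathrm{rank}/\sigma)^2)\), σ = 50,
normalized to sum one over the k neighbors (a uniform 1/k option
exists); neighbor search uses Manhattan distance on range-scaled
predictors; ties break by observation index. The default is an
exhaustive pass (m = n, every observation once, fully deterministic);
random selection with replacement under a seed is available. The
response used for weighting is the *continuous* CI value — the
algorithm is defined for a continuous target even though the
downstream task is binary; a binary-response mode exists.

Two forced consequences serve as self-checks: a constant predictor has
Δj ≡ 0 and therefore weight exactly zero, and a constant response makes
\(W_{dy} = 0\), so the final division is undefined — reported as a
classed "degenerate response" error. The implementation is verified
against an independent nested-loop transcription of the recurrences to
1e-12 over randomized tables. The grouping of the final formula's
second term is the standard RReliefF one; the inline rendering in the
source description is typographically ambiguous, and we implement the
standard reading.

## Classifier, split and evaluation

The classifier is a gradient-boosted decision-tree ensemble whose
summed tree scores are converted to a class by argmax (for two classes,
a 0.5 probability threshold). Boosting internals are delegated to
xgboost behind a pluggable fit/predict contract (`train_classifier`'s
`engine` argument accepts any list with `fit(X, y01, params)` and
`predict(fit, X)`); the package's contribution is the pipeline, not the
boosting algorithm.

Default hyperparameters are sized for tables of a few hundred to a few
thousand windows: 60 rounds of depth-2 trees, learning rate 0.05, and
`min_child_weight = 20` (≈80 rows per leaf under the 0.25
binary-logistic Hessian). The leaf constraint is deliberate: adjacent
windows share 10 s of signal, so a window-unit split leaks
near-duplicate rows across partitions, and an over-parameterized
ensemble simply memorizes each row's twin. Under label permutation such
a model scores near 50 % instead of reverting to the majority rate; the
regularized default restores the base-rate behavior a null model should
have, at no cost on separable data. For tables much smaller than ~150
training rows the leaf constraint prevents any split — lower
`min_child_weight` accordingly.

Splitting follows cumulative rounding of the 0.64/0.16/0.20
train/validation/test fractions (7399 rows → 4735/1184/1480). Two split
units are provided: `window` (the default, matching the overlapping
window scheme described above — with the leakage caveat) and `subject`,
which keeps all windows of a subject in one partition and errors if no
assignment lands within ±5 points of every fraction. For honest
generalization claims on real data, use the subject unit; the window
unit is retained as the faithful default for comparability. Five-fold
cross-validation is stratified by label. No class rebalancing is
applied by default (class weighting is a training option).

Evaluation reports the 2×2 confusion matrix, per-class precision,
recall and F1, and overall accuracy, each raw and rounded to
conventional reporting precision (metrics to two decimals, accuracy as
a percentage with two decimals). Micro-averaged recall equals accuracy
by construction; the tests assert these identities.

## The synthetic cohort generator

Raw paired PPG/thermodilution registries are not publicly depositable,
so the package ships a generator that emulates the statistical
structure the pipeline assumes, and every stage is tested against it.

**Beat model.** A beat is a DC baseline plus two Gaussian lobes
(systolic and dicrotic) in *circular* beat phase — wrapping the lobes
makes the template continuous across beat boundaries, so concatenated
beats join smoothly at the foot instead of leaving a spurious curvature
spike there. The parameter `dicrotic_amplitude_frac` is the
*observable* notch height: the beat value at the notch, measured above
the foot, as a fraction of the systolic peak height. A pure two-lobe
sum cannot place the notch at the nominal lobe gain (the saddle always
sits below it), so the generator calibrates the dicrotic lobe gain by
root-finding on a dense grid of the closed form until the notch height
equals the requested fraction. Parameterizing by the observable keeps
the generator's ground truth in exactly the units the `dPoint/systPeak`
feature ratio measures, which is what makes parameter-recovery tests
meaningful. Extreme settings (high notch fraction with a distant
dicrotic center) produce bifid pulses that a beat detector rightly
sees as two waves; the documentation flags the realistic region.

**Cohort defaults** are the generator's study conditions: 125-Hz PPG;
CI updated every 60 s, recorded at 0.5 Hz, following a reflected
Gaussian random walk on [1.2, 4.0] L/min/m² (start 2.2, near the
median CI reported for this surgical population; step sd 0.35 per
update), which yields roughly one-third Low occupancy; heart rate
60–90 bpm with 2 % beat-to-beat jitter and 3 % amplitude jitter;
additive white noise (sd 0.03 PPG units) plus a 0.2-Hz sinusoidal
baseline wander (amplitude 0.3) to exercise the band-pass and detrend
stages; SpO₂ simulated as 100 minus small positive noise, existing
only to feed `plethSat`. While the CI state is ≤ 2, beat synthesis
switches to a shifted template — by default systolic amplitude × 0.75,
notch fraction × 0.85, systolic timing × 1.08 — so the label is
recoverable from morphology. No quantitative morphology difference
between CO states is published; these effect sizes are free parameters
of the simulation, not claims about physiology.

**What the generator does not emulate:** motion artifacts, arrhythmia,
probe repositioning, vasomotor drift, and any coupling between CI and
heart rate or SpO₂. Passing the synthetic end-to-end test therefore
shows that the pipeline recovers morphology-encoded state differences
of the assumed kind — it does not certify performance on clinical
recordings.

## Numerical choices

* **Resampling.** CI upsampling uses previous-value (zero-order-hold)
  interpolation: thermodilution values are 60-s-cadence measurements
  and intermediate physiology must not be invented. Waveform
  resampling is polyphase FIR (Kaiser-windowed sinc, β = 12, 40 ×
  max(p, q) half-length, reflection padding, integer group-delay
  compensation); a 1-Hz tone survives a 125→25→125 Hz round trip with
  interior error below 1e-3 of amplitude (≈3e-7 measured). End samples
  are extrapolated by odd reflection and carry O((2πf·Δt)³) error.
* **Quantiles** are linear-interpolation (R type 7) throughout.
* **Ties** in Relief neighbor search and in `select_top` break by
  observation/column order, making exhaustive runs fully deterministic.
* **Degenerate inputs** are classed errors, not NA propagation:
  constant responses (Relief), single-class training sets, monotone
  beats, windows with fewer than three beats, empty channels.
* **Seeds.** Every stochastic stage takes an explicit seed; subjects
  derive independent streams from the cohort seed, and the pipeline is
  bit-stable on rerun.

## Problem sizes used by the test suite

The package's own tests exercise the full pipeline at 40 synthetic
subjects × 10 min per record (≈440 windows), averaged over five seeds,
with a label-permutation null alongside; unit tests use 1–8 subjects
and 1–5 min records. These sizes were chosen to make the morphology
effect measurable at tight confidence while keeping a complete test run
in a few minutes on one CPU.

## Known limitations

* The automated quality screen is rule-based and intentionally simple;
  it does not detect motion artifacts with preserved amplitude.
* `plethSat` depends on an auxiliary SpO₂ channel; without one the
  feature (and hence the full 20-feature vector) is unavailable.
* The window-unit split leaks overlapping samples between partitions;
  accuracy under it should be read as within-recording performance.
* The generator's low-state effect sizes are assumptions; real
  morphology differences between CO states may be smaller, larger, or
  differently shaped.
* Features are computed at 125 Hz; other sampling rates are supported
  through resampling, but fiducial resolution scales with the rate.
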