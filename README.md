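# ppgci — cardiac-index state classification from finger photoplethysmography

Continuous cardiac-output monitoring by pulmonary-artery-catheter
thermodilution is the clinical reference for detecting low-output
states, but it is invasive. `ppgci` implements a non-invasive screening
pipeline for anesthesia and critical-care researchers: it classifies
60-second windows of an ordinary finger PPG into **Low**
(cardiac index ≤ 2 L/min/m², the conventional low-cardiac-output
cutoff) versus **NonLow** states, using the morphology of a per-window
ensemble-averaged pulse.

The pipeline:

1. **Records** — paired 125-Hz PPG and 0.5-Hz continuous CI channels
   (plus an SpO₂ numeric), read/written in a plain-text record format,
   or generated by the package's synthetic cohort simulator.
2. **Preprocessing** — rule-based quality screening; 60-s windows with
   10-s overlap (50-s hop); last-CI-in-window reference; Low/NonLow
   labeling; 0.1–15 Hz zero-phase Butterworth band-pass and linear
   detrending.
3. **Representative beat** — prominence-based systolic peak detection,
   foot-to-foot beat segmentation, time-normalized ensemble averaging,
   derivative computation.
4. **Features** — twenty pulse-wave features per window (notch and peak
   amplitudes, derivative landmarks `a1`/`b2`/`c1`, timing intervals,
   perfusion index, spectral entropies, distribution moments, areas…).
5. **Relief weighting** — RReliefF predictor weights for the continuous
   CI response. Per iteration, an observation and its k nearest
   neighbors update three running weights

   ```
   W_dy    += Δy(x_r, x_q) · d_qr
   W_dj    += Δj(x_r, x_q) · d_qr
   W_dy&dj += Δy · Δj · d_qr
   ```

   and after m iterations each predictor j is scored

   ```
   W_j = W_dy&dj / W_dy − (W_dj − W_dy&dj) / (m − W_dy)
   ```

6. **Model & evaluation** — gradient-boosted decision trees (argmax
   over summed tree votes; engine pluggable, xgboost by default),
   64/16/20 train/validation/test split, stratified 5-fold
   cross-validation, confusion-matrix metrics (accuracy, per-class
   precision/recall/F1).

The methods vignette (`vignettes/ppgci-methods.Rmd`) documents every
convention, default and design decision, including what the synthetic
generator does and does not emulate.

## Worked example

Simulate a 40-subject cohort (10 minutes of paired PPG/CI per subject),
run the full pipeline, and evaluate on the held-out test windows:

```r
library(ppgci)

cfg <- pipeline_config(
  cohort = cohort_params(n_subjects = 40, record_duration = 600, seed = 7),
  seed = 7)
res <- run_pipeline(cfg)

nrow(res$feature_table)        # 440 windows
res$cv$mean_accuracy           # 0.9644
print(res$test_report)
```

```
<evaluation_report>  n = 88, accuracy = 95.45%
        predicted
truth    Low NonLow
  Low     27      1
  NonLow   3     57
  class total correct precision recall   f1
    Low    28      27      0.90   0.96 0.93
 NonLow    60      57      0.98   0.95 0.97
```

```r
head(res$relief$ranking, 5)
#> "diff2Quant25" "plethPerf" "areaTotal" "fftMean" "systPeak"
```

Reading the output: 440 windows were extracted (34.8 % labeled Low by
the simulated CI process); the classifier recovers the low-state
morphology shift on unseen windows with 95.45 % accuracy, balanced
across classes (F1 0.93 Low / 0.97 NonLow); and Relief ranks
amplitude- and curvature-scale features highest — exactly the features
the simulator's low-state effect perturbs. On real recordings, prefer
`split_unit = "subject"` to avoid the overlap leakage discussed in the
vignette.

A thin command-line front end is included at `inst/cli/ppgci`
(subcommands `simulate`, `extract`, `rank`, `train`, `evaluate`,
`run-all`).

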