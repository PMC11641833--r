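rb_from_train <- function(tpl, period = 0.8, rate = 125, n_beats = 70) {
  x <- make_pulse_train(tpl, period, rate, n_beats)
  average_beats(extract_beats(x, detect_peaks(x, rate)), rate)
}

test_that("fiducials land within 3 samples of the dense-grid landmarks", {
  cases <- list(
    beat_template_params(),
    beat_template_params(systolic_time_frac = 0.18,
                         dicrotic_amplitude_frac = 0.3,
                         dicrotic_time_frac = 0.5,
                         pulse_widths = c(0.08, 0.11)),
    beat_template_params(dicrotic_amplitude_frac = 0.35,
                         dicrotic_time_frac = 0.58,
                         pulse_widths = c(0.11, 0.16)),
    beat_template_params(dicrotic_amplitude_frac = 0.5,
                         dicrotic_time_frac = 0.52))
  for (tpl in cases) {
    rb <- rb_from_train(tpl)
    fid <- detect_fiducials(rb)
    truth <- oracle_beat_landmarks(tpl, 0.8, 125)
    for (nm in c("systolic_peak_idx", "dicrotic_notch_idx", "a1_idx",
                 "b2_idx", "c1_idx")) {
      expect_lte(abs(fid[[nm]] - truth[[nm]]), 3,
                 label = sprintf("%s (got %d, expected %d)", nm,
                                 fid[[nm]], truth[[nm]]))
    }
  }
})

test_that("fiducial ordering invariants hold, including the notch-free fallback", {
  tpl <- beat_template_params(dicrotic_amplitude_frac = 0)
  rb <- rb_from_train(tpl)
  fid <- detect_fiducials(rb)
  expect_true(fid$foot_idx < fid$a1_idx)
  expect_true(fid$a1_idx < fid$systolic_peak_idx)
  expect_true(fid$systolic_peak_idx < fid$dicrotic_notch_idx)
  expect_lte(fid$dicrotic_notch_idx, length(rb$samples))
  expect_gt(fid$b2_idx, fid$a1_idx)
})

test_that("degenerate beats raise a fiducial error", {
  flat <- structure(list(samples = rep(1, 100), d1 = rep(0, 100),
                         d2 = rep(0, 100), beat_count = 5,
                         mean_period = 0.8, rate = 125),
                    class = "representative_beat")
  expect_error(detect_fiducials(flat), class = "ppgci_fiducial_error")
  mono <- structure(list(samples = seq(0, 1, length.out = 100),
                         d1 = rep(1, 100), d2 = rep(0, 100),
                         beat_count = 5, mean_period = 0.8, rate = 125),
                    class = "representative_beat")
  expect_error(detect_fiducials(mono), class = "ppgci_fiducial_error")
})

test_that("dPoint/systPeak recovers the generating notch fraction within 0.02", {
  for (frac in c(0.3, 0.4, 0.5)) {
    tpl <- beat_template_params(dicrotic_amplitude_frac = frac)
    rb <- rb_from_train(tpl)
    fid <- detect_fiducials(rb)
    s <- rb$samples
    ratio <- (s[fid$dicrotic_notch_idx] - s[fid$foot_idx]) /
      (s[fid$systolic_peak_idx] - s[fid$foot_idx])
    expect_lt(abs(ratio - frac), 0.02)
  }
})

test_that("plethHr recovers the generating heart rate", {
  for (period in c(0.8, 1.0)) {
    tpl <- beat_template_params()
    rb <- rb_from_train(tpl, period = period, n_beats = 60)
    fid <- detect_fiducials(rb)
    w <- make_window(make_pulse_train(tpl, period, 125, 60))
    f <- compute_features(w, rb, fid)
    expect_lte(abs(f[["plethHr"]] - 60 / period), 1)
  }
})

test_that("a value-symmetric beat has near-zero skewness", {
  s <- 1 + sin(2 * pi * (0:99) / 100)
  rb <- structure(list(samples = s,
                       d1 = c(diff(s), 0), d2 = c(0, diff(s, differences = 2), 0),
                       beat_count = 10, mean_period = 0.8, rate = 125),
                  class = "representative_beat")
  skew <- e1071::skewness(rb$samples, type = 1)
  expect_lt(abs(skew), 0.01)
})

test_that("spectral entropy orders tonal, two-tone and broadband signals", {
  rate <- 125
  t <- (0:4095) / rate
  tone <- sin(2 * pi * 4 * t)
  two <- sin(2 * pi * 4 * t) + sin(2 * pi * 11 * t)
  noise <- withr::with_seed(3, rnorm(4096))
  h1 <- spectral_entropy(tone[1:512], rate)
  h2 <- spectral_entropy(two, rate)
  h3 <- spectral_entropy(noise, rate)
  expect_lt(h1, 0.25)
  expect_gt(h3, 0.9)
  expect_gt(h2, spectral_entropy(tone, rate))
  expect_lt(h2, h3)
  expect_true(all(c(h1, h2, h3) >= 0 & c(h1, h2, h3) <= 1))
  expect_error(spectral_entropy(rnorm(8), rate),
               class = "ppgci_input_error")
})

test_that("features transform correctly under an amplitude scale", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 14)
  rec <- simulate_subject(cp, 1)
  w <- segment_windows(rec, NULL)[[1]]
  rb <- representative_beat(w)
  f1 <- compute_features(w, rb, detect_fiducials(rb))

  cc <- 2.5
  w2 <- w
  w2$ppg_filtered <- cc * w$ppg_filtered
  w2$ppg_raw <- cc * w$ppg_raw
  rb2 <- representative_beat(w2)
  f2 <- compute_features(w2, rb2, detect_fiducials(rb2))

  linear <- c("dPoint", "systPeak", "Featb2", "c1", "fftMean",
              "diff2Quant25", "diff2IQR", "areaTotal", "area2")
  invariant <- c("plethSkewness", "plethKurtosis", "plethPeakRms",
                 "plethSpecEntropy", "diff1SpecEntropy",
                 "diff2SpecEntropy", "plethHr", "Ta1", "tpt", "plethSat",
                 "plethPerf")
  for (nm in linear)
    expect_equal(f2[[nm]], cc * f1[[nm]], tolerance = 1e-6, label = nm)
  for (nm in invariant)
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
})

test_that("areaTotal dominates area2 across simulated windows", {
  cp <- cohort_params(n_subjects = 3, record_duration = 180, seed = 15)
  ft <- build_feature_table(simulate_cohort(cp))
  expect_true(all(ft$areaTotal >= ft$area2))
  expect_true(all(ft$area2 >= 0))
  expect_true(all(is.finite(as.matrix(ft[, ppg_feature_names]))))
})

test_that("the feature table has the canonical schema and row order", {
  cp <- cohort_params(n_subjects = 2, record_duration = 230, seed = 17)
  recs <- simulate_cohort(cp)
  ft <- build_feature_table(recs)
  expect_identical(names(ft)[1:20], ppg_feature_names)
  ord <- order(ft$subject_id, ft$start_time)
  expect_identical(ord, seq_len(nrow(ft)))
  expect_true(all(!is.na(ft)))

  # knocking out one window drops exactly one row, with a logged reason
  rec <- recs[[1]]
  idx <- (70 * 125 + 1):(75 * 125)       # inside the 50-110 s window only
  rec$ppg$values[idx] <- rec$ppg$values[idx[1]]
  ft2 <- build_feature_table(list(rec))
  n_windows <- length(segment_windows(recs[[1]], NULL))
  expect_identical(nrow(ft2), n_windows - 1L)
})

test_that("feature tables round-trip through CSV", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 18)
  ft <- build_feature_table(simulate_cohort(cp))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(names(back), names(ft))
  expect_equal(back$systPeak, ft$systPeak, tolerance = 1e-12)
  expect_identical(as.character(back$label), as.character(ft$label))
})
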