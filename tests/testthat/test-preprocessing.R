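test_that("a clean synthetic record passes the quality screen", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 4)
  rec <- simulate_subject(cp, 1)
  expect_true(all(screen_quality(rec)))
})

test_that("flat-line runs are flagged within one sample of their span", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 4)
  rec <- simulate_subject(cp, 1)
  i0 <- 3001L; i1 <- i0 + 5L * 125L - 1L     # 5-s flat-line
  rec$ppg$values[i0:i1] <- rec$ppg$values[i0]
  mask <- screen_quality(rec)
  inv <- which(!mask)
  expect_gte(min(inv), i0 - 1L)
  expect_lte(max(inv), i1 + 1L)
  expect_gte(length(inv), 5L * 125L - 2L)
})

test_that("an all-gap record yields an all-invalid mask", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 4)
  rec <- simulate_subject(cp, 1)
  rec$ppg$values[] <- NA_real_
  expect_false(any(screen_quality(rec)))
})

test_that("amplitude outliers beyond 6 robust SD are flagged", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 4)
  rec <- simulate_subject(cp, 1)
  spike <- c(800L, 9000L)
  rec$ppg$values[spike] <- max(rec$ppg$values) * 50
  mask <- screen_quality(rec)
  expect_true(all(!mask[spike]))
  expect_gt(mean(mask), 0.99)
})

test_that("window starts follow the 50-s hop and short records yield fewer windows", {
  for (case in list(list(dur = 170, n = 3), list(dur = 60, n = 1),
                    list(dur = 59, n = 0))) {
    cp <- cohort_params(n_subjects = 1, record_duration = max(case$dur, 60),
                        seed = 6)
    rec <- simulate_subject(cp, 1)
    keep <- seq_len(round(case$dur * 125))
    rec$ppg$values <- rec$ppg$values[keep]
    wins <- segment_windows(rec, NULL)
    expect_length(wins, case$n)
    if (case$n > 0)
      expect_equal(vapply(wins, `[[`, numeric(1), "start_time"),
                   seq(0, by = 50, length.out = case$n))
  }
})

test_that("window count per contiguous valid span matches floor((span-60)/50)+1", {
  cp <- cohort_params(n_subjects = 1, record_duration = 400, seed = 16)
  rec <- simulate_subject(cp, 1)
  for (dur in c(110, 160, 210, 335, 400)) {
    r <- rec
    r$ppg$values <- r$ppg$values[seq_len(round(dur * 125))]
    expect_length(segment_windows(r, NULL), floor((dur - 60) / 50) + 1)
  }
})

test_that("the reference CI is the last value inside the half-open span", {
  ci <- list(time = c(30, 55), values = c(2.4, 1.8))
  expect_identical(assign_reference_ci(0, 60, ci), 1.8)
  expect_identical(assign_reference_ci(0, 60,
                                       list(time = 10, values = 2.2)), 2.2)
  expect_error(assign_reference_ci(60, 120, ci),
               class = "ppgci_missing_reference")
})

test_that("labeling is boundary-inclusive at 2 L/min/m^2", {
  expect_identical(as.character(label_window(2.0)), "Low")
  expect_identical(as.character(label_window(2.3)), "NonLow")
  expect_identical(as.character(label_window(1.99)), "Low")
  expect_error(label_window(-1), class = "ppgci_parameter_error")
})

test_that("the band-pass rejects DC and attenuates out-of-band tones", {
  rate <- 125
  x_dc <- rep(3, 7500)
  expect_lt(max(abs(bandpass_filter(x_dc, rate))), 1e-6 * 3)

  t <- (0:7499) / rate
  trim <- 626:6875
  y1 <- bandpass_filter(sin(2 * pi * 1 * t), rate)
  expect_lt(abs(max(abs(y1[trim])) - 1), 0.05)

  y30 <- bandpass_filter(sin(2 * pi * 30 * t), rate)
  expect_lt(max(abs(y30[trim])), 0.2)

  expect_error(bandpass_filter(x_dc, rate, low = 0.1, high = 70),
               class = "ppgci_parameter_error")
})

test_that("detrending removes constants, ramps and mixed linear trends", {
  expect_equal(detrend_signal(rep(5, 100)), rep(0, 100), tolerance = 1e-12)
  ramp <- seq(0, 10, length.out = 500)
  expect_lt(max(abs(detrend_signal(ramp))), 1e-9 * 10)
  s <- sin(2 * pi * 3 * (0:2499) / 125)
  mixed <- s + seq(-4, 4, length.out = 2500)
  expect_gt(cor(detrend_signal(mixed), s), 0.999)
  expect_equal(mean(detrend_signal(mixed)), 0, tolerance = 1e-9)
})

test_that("filter + detrend is numerically idempotent", {
  cp <- cohort_params(n_subjects = 1, record_duration = 120, seed = 8)
  rec <- simulate_subject(cp, 1)
  w <- segment_windows(rec, NULL)[[1]]
  once <- w$ppg_filtered
  twice <- detrend_signal(bandpass_filter(once, 125))
  interior <- 626:6875     # 5 s trimmed per end: high-pass edge transient
  # residual 0.2 Hz wander sits on the high-pass shoulder (|H| < 1), so a
  # second pass removes a little more of it; 5% bounds that shoulder loss
  expect_lt(max(abs(twice - once)[interior]) / diff(range(once)), 0.05)
})

test_that("windows carry consistent labels and reference values", {
  cp <- cohort_params(n_subjects = 2, record_duration = 300, seed = 10)
  for (rec in simulate_cohort(cp)) {
    for (w in segment_windows(rec, screen_quality(rec))) {
      expect_length(w$ppg_raw, 7500L)
      expect_length(w$ppg_filtered, 7500L)
      expect_gt(w$reference_ci, 0)
      expect_identical(as.character(w$label),
                       if (w$reference_ci <= 2) "Low" else "NonLow")
    }
  }
})
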