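# Synthetic paired PPG / cardiac-index records.
#
# The beat model is a DC baseline plus two Gaussian lobes (systolic and
# dicrotic) in normalized beat time.  The dicrotic lobe gain is calibrated
# at construction so that the *observable* notch height -- the beat value at
# the local minimum between the lobes, measured above the foot -- equals
# `dicrotic_amplitude_frac` times the systolic peak height.  Parameterizing
# by the observable keeps the generator's ground truth in the same units as
# the dPoint/systPeak features measured downstream.

# Gaussian lobes in circular (wrapped) beat phase, so the template is
# continuous across beat boundaries and concatenated beats join smoothly
# at the foot.
beat_mixture <- function(frac, m1, w1, m2, w2, gain) {
  wrap <- function(d) {
    dd <- abs(d) %% 1
    pmin(dd, 1 - dd)
  }
  exp(-0.5 * (wrap(frac - m1) / w1)^2) +
    gain * exp(-0.5 * (wrap(frac - m2) / w2)^2)
}

# dense-grid shape analysis of the closed-form mixture (normalized time)
beat_shape <- function(m1, w1, m2, w2, gain, n_grid = 8192L) {
  f <- seq(0, 1, length.out = n_grid)
  s <- beat_mixture(f, m1, w1, m2, w2, gain)
  d <- diff(s)
  pk <- which.max(s)
  mins <- which(d[-1] > 0 & d[-length(d)] < 0) + 1L
  mins <- mins[mins > pk]
  maxs <- which(d[-1] < 0 & d[-length(d)] > 0) + 1L
  notch <- if (length(mins)) mins[1L] else NA_integer_
  sec <- if (!is.na(notch)) {
    cand <- maxs[maxs > notch]
    if (length(cand)) cand[1L] else NA_integer_
  } else NA_integer_
  list(
    peak_frac = f[pk],
    notch_frac = if (is.na(notch)) NA_real_ else f[notch],
    secondary_frac = if (is.na(sec)) NA_real_ else f[sec],
    # foot convention: the waveform minimum, matching the foot the beat
    # segmentation detects downstream
    notch_ratio = if (is.na(notch)) NA_real_ else
      (s[notch] - min(s)) / (s[pk] - min(s))
  )
}

# solve for the dicrotic lobe gain whose notch height fraction is `target`
calibrate_dicrotic_gain <- function(target, m1, w1, m2, w2) {
  if (target < 1e-6) return(0)
  ratio_at <- function(g) beat_shape(m1, w1, m2, w2, g)$notch_ratio
  lo <- 0.02; hi <- 0.98
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)
  # shrink the bracket away from ends where the notch degenerates
  while (is.na(r_hi) && hi > lo + 0.05) { hi <- hi - 0.05; r_hi <- ratio_at(hi) }
  while (is.na(r_lo) && lo < hi - 0.05) { lo <- lo + 0.05; r_lo <- ratio_at(lo) }
  if (is.na(r_lo) || is.na(r_hi) || target < r_lo || target > r_hi)
    ppgci_error("ppgci_parameter_error", sprintf(
      "requested notch height fraction %.3g is unreachable for this lobe geometry (achievable: %.3g-%.3g)",
      target, r_lo, r_hi))
  stats::uniroot(function(g) ratio_at(g) - target, c(lo, hi),
                 tol = 1e-9)$root
}

#' Beat template parameters for the synthetic PPG generator
#'
#' Defines a single-beat waveform as a DC baseline plus two Gaussian lobes
#' in normalized beat time: a systolic lobe and a dicrotic (reflected-wave)
#' lobe whose gain is calibrated so the notch height above the foot equals
#' `dicrotic_amplitude_frac` of the systolic peak height.
#'
#' @param systolic_amplitude Peak pulsatile amplitude, arbitrary PPG units
#'   (> 0).
#' @param systolic_time_frac Center of the systolic lobe as a fraction of
#'   the beat period, in (0, 1).
#' @param dicrotic_amplitude_frac Target notch height as a fraction of the
#'   systolic peak height (both measured above the foot), in \[0, 1).
#'   A value of 0 degenerates to a single-lobe (notch-free) beat.
#' @param dicrotic_time_frac Center of the dicrotic lobe, a fraction of the
#'   beat period strictly greater than `systolic_time_frac`.
#' @param pulse_widths Gaussian widths (sd) of the systolic and dicrotic
#'   lobes, fractions of the beat period, both > 0.
#' @param dc_level Baseline (DC) offset in PPG units, >= 0.
#'
#' @return An object of class `beat_template_params`; the calibrated
#'   dicrotic lobe gain is stored in `$dicrotic_gain`.
#'
#' @details High notch fractions combined with a dicrotic center far from
#'   the systolic one require a large lobe gain and produce a bifid
#'   (double-peaked) pulse whose secondary wave a beat detector will
#'   treat as a beat of its own; keep `dicrotic_time_frac` within about
#'   0.3 of `systolic_time_frac` for waveforms with a conventional
#'   notch-and-shoulder morphology.
#' @examples
#' tpl <- beat_template_params()
#' beat <- simulate_beat(tpl, period = 0.8, rate = 125)
#' length(beat) # 100 samples
#' @export
beat_template_params <- function(systolic_amplitude = 1,
                                 systolic_time_frac = 0.22,
                                 dicrotic_amplitude_frac = 0.42,
                                 dicrotic_time_frac = 0.55,
                                 pulse_widths = c(0.10, 0.12),
                                 dc_level = 1) {
  check_number(systolic_amplitude, "systolic_amplitude", lower = 0,
               strict_lower = TRUE)
  check_number(systolic_time_frac, "systolic_time_frac", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(dicrotic_amplitude_frac, "dicrotic_amplitude_frac", 0, 1,
               strict_upper = TRUE)
  check_number(dicrotic_time_frac, "dicrotic_time_frac",
               lower = systolic_time_frac, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (length(pulse_widths) != 2L || !all(is.finite(pulse_widths)) ||
      any(pulse_widths <= 0))
    ppgci_error("ppgci_parameter_error",
                "`pulse_widths` must be two positive numbers")
  check_number(dc_level, "dc_level", lower = 0)
  gain <- calibrate_dicrotic_gain(dicrotic_amplitude_frac,
                                  systolic_time_frac, pulse_widths[1L],
                                  dicrotic_time_frac, pulse_widths[2L])
  structure(
    list(systolic_amplitude = systolic_amplitude,
         systolic_time_frac = systolic_time_frac,
         dicrotic_amplitude_frac = dicrotic_amplitude_frac,
         dicrotic_time_frac = dicrotic_time_frac,
         pulse_widths = as.numeric(pulse_widths),
         dc_level = dc_level,
         dicrotic_gain = gain),
    class = "beat_template_params")
}

#' Synthesize one PPG beat
#'
#' Evaluates the two-Gaussian beat template over one beat period.
#'
#' @param params A [beat_template_params()] object.
#' @param period Beat period in seconds, in \[0.3, 2\].
#' @param rate Sampling rate in Hz, >= 50.
#' @param amplitude_scale Optional multiplicative scale on the pulsatile
#'   component (the DC baseline is unaffected); used for beat-to-beat
#'   amplitude variability.
#'
#' @return Numeric vector of `round(period * rate)` samples.
#' @export
simulate_beat <- function(params, period, rate, amplitude_scale = 1) {
  if (!inherits(params, "beat_template_params"))
    ppgci_error("ppgci_parameter_error",
                "`params` must be a `beat_template_params` object")
  check_number(period, "period", 0.3, 2)
  check_number(rate, "rate", lower = 50)
  check_number(amplitude_scale, "amplitude_scale", lower = 0,
               strict_lower = TRUE)
  n <- round(period * rate)
  frac <- (seq_len(n) - 1) / n
  params$dc_level + params$systolic_amplitude * amplitude_scale *
    beat_mixture(frac, params$systolic_time_frac, params$pulse_widths[1L],
                 params$dicrotic_time_frac, params$pulse_widths[2L],
                 params$dicrotic_gain)
}

#' Cohort-level parameters for the synthetic generator
#'
#' Collects every setting of the paired PPG / cardiac-index simulation:
#' acquisition rates (PPG 125 Hz; CI updated every 60 s, recorded at
#' 0.5 Hz), heart-rate range, the bounded Gaussian random walk used for the
#' CI process (reflected into `ci_bounds`), the multiplicative morphology
#' shifts applied while the CI state is at or below `ci_threshold`, and the
#' noise model (additive white Gaussian noise plus one low-frequency
#' sinusoidal baseline wander).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param record_duration Record length per subject in seconds (>= 60).
#' @param ppg_rate PPG sampling rate in Hz (must exceed twice the 15 Hz
#'   band-pass upper edge).
#' @param co_record_rate Rate at which the CI channel is recorded, Hz.
#' @param co_update_period Seconds between CI value updates.
#' @param hr_range Two-element range of subject base heart rates, beats/min.
#' @param ci_start,ci_step_sd,ci_bounds Start value, per-update step sd and
#'   reflecting bounds of the CI random walk, L/min/m^2.
#' @param ci_threshold CI at or below which the low-state morphology applies,
#'   L/min/m^2.
#' @param low_state_effect Named multipliers applied to the beat template
#'   fields while the CI state is low. Names must be fields of
#'   [beat_template_params()].
#' @param noise_sd Additive white-noise sd, PPG units.
#' @param baseline_wander Named vector `c(amplitude =, frequency =)` of the
#'   sinusoidal wander (PPG units, Hz).
#' @param hr_jitter,amp_jitter Relative sd of beat-to-beat period and
#'   amplitude variability.
#' @param beat_template Baseline [beat_template_params()].
#' @param seed Integer seed; every subject derives its own stream from it.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 10L,
                          record_duration = 600,
                          ppg_rate = 125,
                          co_record_rate = 0.5,
                          co_update_period = 60,
                          hr_range = c(60, 90),
                          ci_start = 2.2,
                          ci_step_sd = 0.35,
                          ci_bounds = c(1.2, 4.0),
                          ci_threshold = 2.0,
                          low_state_effect = c(systolic_amplitude = 0.75,
                                               dicrotic_amplitude_frac = 0.85,
                                               systolic_time_frac = 1.08),
                          noise_sd = 0.03,
                          baseline_wander = c(amplitude = 0.3,
                                              frequency = 0.2),
                          hr_jitter = 0.02,
                          amp_jitter = 0.03,
                          beat_template = beat_template_params(),
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 0)
  check_number(record_duration, "record_duration", lower = 0,
               strict_lower = TRUE)
  check_number(ppg_rate, "ppg_rate", lower = 30, strict_lower = TRUE)
  check_number(co_record_rate, "co_record_rate", lower = 0,
               strict_lower = TRUE)
  check_number(co_update_period, "co_update_period", lower = 0,
               strict_lower = TRUE)
  stopifnot(length(hr_range) == 2L, hr_range[1] > 0,
            hr_range[2] >= hr_range[1],
            length(ci_bounds) == 2L, ci_bounds[1] > 0,
            ci_bounds[2] > ci_bounds[1])
  if (!is.null(low_state_effect) && length(low_state_effect)) {
    bad <- setdiff(names(low_state_effect),
                   c("systolic_amplitude", "systolic_time_frac",
                     "dicrotic_amplitude_frac", "dicrotic_time_frac",
                     "pulse_widths", "dc_level"))
    if (length(bad))
      ppgci_error("ppgci_parameter_error", paste(
        "unknown `low_state_effect` fields:", paste(bad, collapse = ", ")))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         record_duration = record_duration, ppg_rate = ppg_rate,
         co_record_rate = co_record_rate,
         co_update_period = co_update_period,
         hr_range = hr_range, ci_start = ci_start, ci_step_sd = ci_step_sd,
         ci_bounds = ci_bounds, ci_threshold = ci_threshold,
         low_state_effect = low_state_effect, noise_sd = noise_sd,
         baseline_wander = baseline_wander, hr_jitter = hr_jitter,
         amp_jitter = amp_jitter, beat_template = beat_template,
         seed = as.integer(seed)),
    class = "cohort_params")
}

reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- lo + (lo - x)
    if (x > hi) x <- hi - (x - hi)
  }
  x
}

apply_low_effect <- function(template, effect) {
  if (is.null(effect) || !length(effect)) return(template)
  args <- template[c("systolic_amplitude", "systolic_time_frac",
                     "dicrotic_amplitude_frac", "dicrotic_time_frac",
                     "pulse_widths", "dc_level")]
  for (nm in names(effect)) args[[nm]] <- args[[nm]] * effect[[nm]]
  do.call(beat_template_params, args)
}

#' Simulate one subject's paired PPG / cardiac-index record
#'
#' The PPG is a concatenation of beats whose period is drawn around the
#' subject's base heart rate; beats synthesized while the CI state is at or
#' below `ci_threshold` use the low-state-shifted template, so the window
#' label is recoverable from waveform morphology. Baseline wander and white
#' noise are added afterwards. The CI series is a bounded random walk,
#' piecewise constant per update period and recorded at `co_record_rate`.
#' Fully deterministic given `cohort$seed` and `subject_index`.
#'
#' @param cohort A [cohort_params()] object.
#' @param subject_index Positive integer identifying the subject; also used
#'   to derive the subject's RNG stream.
#'
#' @return An object of class `subject_record` with fields `subject_id`,
#'   `ppg` (values + rate), `ci` (time, values, rate), `spo2`, `meta`, and
#'   the generator ground truth `ci_updates` / `low_truth`.
#' @export
simulate_subject <- function(cohort, subject_index) {
  if (!inherits(cohort, "cohort_params"))
    ppgci_error("ppgci_parameter_error",
                "`cohort` must be a `cohort_params` object")
  check_number(subject_index, "subject_index", lower = 1)
  if (cohort$record_duration < 60)
    ppgci_error("ppgci_input_error",
                "`record_duration` must cover at least one 60-s window")
  seed_i <- (cohort$seed %% 2147483647L + 7919L * as.integer(subject_index)) %%
    2147483647L
  with_seed(seed_i, {
    dur <- cohort$record_duration
    rate <- cohort$ppg_rate
    n_total <- round(dur * rate)

    # CI process: reflected Gaussian random walk, one value per update period
    n_upd <- ceiling(dur / cohort$co_update_period)
    ci_upd <- numeric(n_upd)
    ci_upd[1L] <- reflect_into(
      cohort$ci_start + rnorm(1L, 0, cohort$ci_step_sd),
      cohort$ci_bounds[1L], cohort$ci_bounds[2L])
    for (i in seq_len(n_upd - 1L))
      ci_upd[i + 1L] <- reflect_into(
        ci_upd[i] + rnorm(1L, 0, cohort$ci_step_sd),
        cohort$ci_bounds[1L], cohort$ci_bounds[2L])
    low_upd <- ci_upd <= cohort$ci_threshold

    ci_time <- seq(0, by = 1 / cohort$co_record_rate,
                   length.out = round(dur * cohort$co_record_rate))
    ci_vals <- ci_upd[pmin(floor(ci_time / cohort$co_update_period) + 1L,
                           n_upd)]

    base_hr <- runif(1L, cohort$hr_range[1L], cohort$hr_range[2L])
    tpl_lo <- apply_low_effect(cohort$beat_template, cohort$low_state_effect)

    ppg <- numeric(0)
    t_beat <- 0
    while (length(ppg) < n_total) {
      period <- 60 / (base_hr * (1 + rnorm(1L, 0, cohort$hr_jitter)))
      period <- min(max(period, 0.3), 2)
      upd_idx <- min(floor(t_beat / cohort$co_update_period) + 1L, n_upd)
      tpl <- if (low_upd[upd_idx]) tpl_lo else cohort$beat_template
      amp <- exp(rnorm(1L, 0, cohort$amp_jitter))
      ppg <- c(ppg, simulate_beat(tpl, period, rate, amplitude_scale = amp))
      t_beat <- length(ppg) / rate
    }
    ppg <- ppg[seq_len(n_total)]

    tt <- (seq_len(n_total) - 1) / rate
    bw <- cohort$baseline_wander
    ppg <- ppg +
      bw[["amplitude"]] * sin(2 * pi * bw[["frequency"]] * tt +
                                runif(1L, 0, 2 * pi)) +
      rnorm(n_total, 0, cohort$noise_sd)

    spo2_time <- ci_time
    spo2_vals <- pmin(100 - abs(rnorm(length(spo2_time), 1, 0.5)), 100)

    meta <- list(age = round(runif(1L, 45, 80)),
                 sex = sample(c("M", "F"), 1L, prob = c(0.78, 0.22)),
                 height = round(runif(1L, 150, 185), 1),
                 weight = round(runif(1L, 50, 95), 1))

    structure(
      list(subject_id = sprintf("S%03d", as.integer(subject_index)),
           ppg = list(values = ppg, rate = rate),
           ci = list(time = ci_time, values = ci_vals,
                     rate = cohort$co_record_rate),
           spo2 = list(time = spo2_time, values = spo2_vals,
                       rate = cohort$co_record_rate),
           meta = meta,
           ci_updates = ci_upd, low_truth = low_upd,
           base_hr = base_hr),
      class = "subject_record")
  })
}

#' Simulate a cohort of subject records
#'
#' @param cohort A [cohort_params()] object.
#' @return List of [simulate_subject()] records, length `cohort$n_subjects`.
#' @examples
#' recs <- simulate_cohort(cohort_params(n_subjects = 2, record_duration = 120))
#' length(recs)
#' @export
simulate_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort_params"))
    ppgci_error("ppgci_parameter_error",
                "`cohort` must be a `cohort_params` object")
  lapply(seq_len(cohort$n_subjects),
         function(i) simulate_subject(cohort, i))
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s>  PPG: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$ppg$values), x$ppg$rate,
              length(x$ppg$values) / x$ppg$rate))
  cat(sprintf("  CI: %d values @ %g Hz, range %.2f-%.2f L/min/m^2\n",
              length(x$ci$values), x$ci$rate,
              min(x$ci$values), max(x$ci$values)))
  invisible(x)
}
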