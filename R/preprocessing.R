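# Quality screening, windowing, reference-CI assignment, labeling and
# per-window PPG conditioning.

#' Automated quality screen for a subject record
#'
#' Replaces manual inspection with explicit rules. A PPG sample is marked
#' invalid when it is (a) a missing-sample gap, (b) inside a flat-line run
#' longer than `flat_max_s` seconds (zero sample-to-sample variation),
#' (c) beyond `outlier_sd` robust standard deviations (1.4826 x MAD) of the
#' record median, or (d) inside a CI recording gap.
#'
#' @param record A `subject_record`.
#' @param flat_max_s Longest tolerated flat-line run, seconds.
#' @param outlier_sd Robust-SD multiple for the amplitude outlier rule.
#' @return Logical vector, `TRUE` = valid, same length as the PPG channel.
#' @export
screen_quality <- function(record, flat_max_s = 2, outlier_sd = 6) {
  x <- record$ppg$values
  rate <- record$ppg$rate
  valid <- is.finite(x)

  # flat-line runs: consecutive zero first-differences
  if (length(x) > 1L) {
    flat <- c(FALSE, diff(x) == 0)
    r <- rle(flat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths > flat_max_s * rate)) {
      # a run of k zero diffs spans k+1 identical samples
      valid[(starts[j] - 1L):ends[j]] <- FALSE
    }
  }

  med <- median(x, na.rm = TRUE)
  rsd <- mad(x, na.rm = TRUE)
  if (is.finite(rsd) && rsd > 0)
    valid <- valid & is.finite(x) & abs(x - med) <= outlier_sd * rsd

  # CI gaps invalidate the PPG span they should have covered
  if (!is.null(record$ci)) {
    gap_t <- record$ci$time[!is.finite(record$ci$values)]
    for (t0 in gap_t) {
      i0 <- floor(t0 * rate) + 1L
      i1 <- min(ceiling((t0 + 1 / record$ci$rate) * rate), length(x))
      if (i0 <= length(x)) valid[i0:i1] <- FALSE
    }
  }
  valid
}

#' Reference cardiac index for a window span
#'
#' Returns the CI value with the latest timestamp inside the half-open
#' window span `[start, end)` -- the last recorded value within the
#' window's timeframe.
#'
#' @param start,end Window span in seconds.
#' @param ci CI channel: list with `time` and `values`.
#' @return The reference CI in L/min/m^2.
#' @export
assign_reference_ci <- function(start, end, ci) {
  in_span <- ci$time >= start & ci$time < end & is.finite(ci$values)
  if (!any(in_span))
    ppgci_error("ppgci_missing_reference",
                sprintf("no CI value inside window [%g, %g)", start, end))
  ci$values[max(which(in_span))]
}

#' Label a window from its reference cardiac index
#'
#' `Low` iff CI <= `threshold` (boundary inclusive), otherwise `NonLow`.
#'
#' @param ci Reference CI, L/min/m^2 (finite, > 0).
#' @param threshold Class threshold, default 2 L/min/m^2.
#' @return Factor with levels `c("Low", "NonLow")`.
#' @export
label_window <- function(ci, threshold = 2.0) {
  if (!all(is.finite(ci)) || any(ci <= 0))
    ppgci_error("ppgci_parameter_error", "`ci` must be finite and positive")
  factor(ifelse(ci <= threshold, "Low", "NonLow"),
         levels = c("Low", "NonLow"))
}

#' Zero-phase band-pass filter for PPG windows
#'
#' Second-order Butterworth band-pass applied forward-backward
#' (zero-phase), so fiducial timings are not shifted. The window mean is
#' removed before filtering and the signal is reflection-padded, which
#' suppresses the edge transients of plain forward-backward filtering.
#'
#' @param x Samples.
#' @param rate Sampling rate, Hz (must exceed `2 * high`).
#' @param low,high Band edges in Hz.
#' @param order Butterworth section order.
#' @return Filtered samples, same length as `x`.
#' @export
bandpass_filter <- function(x, rate = 125, low = 0.1, high = 15, order = 2) {
  if (low <= 0 || high <= low || high >= rate / 2)
    ppgci_error("ppgci_parameter_error",
                "band edges must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  xc <- x - mean(x)
  n <- length(xc)
  pad <- min(n - 1L, 3L * rate)
  xp <- c(2 * xc[1L] - xc[(pad + 1L):2L], xc,
          2 * xc[n] - xc[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

#' Remove the best-fit linear trend
#'
#' Least-squares line removal per window (mean removal alone is available
#' with `linear = FALSE`).
#'
#' @param x Samples (>= 2).
#' @param linear Remove the fitted line (`TRUE`) or only the mean.
#' @return Detrended samples with zero mean.
#' @export
detrend_signal <- function(x, linear = TRUE) {
  if (length(x) < 2L)
    ppgci_error("ppgci_input_error", "need at least 2 samples to detrend")
  if (!linear) return(x - mean(x))
  t <- seq_along(x)
  as.numeric(stats::.lm.fit(cbind(1, t), x)$residuals)
}

#' Cut a record into labeled analysis windows
#'
#' Windows are `window_len` seconds long and consecutive windows share
#' `overlap` seconds, i.e. the hop is `window_len - overlap` (60 - 10 =
#' 50 s by default). Window spans are half-open `[start, start + 60)` with
#' starts at 0, 50, 100, ... s. A window is emitted only when every PPG
#' sample in it is valid under `mask` and at least one CI value lies in its
#' span. Each emitted window carries the raw PPG, the band-passed and
#' detrended PPG, the last-in-window reference CI, its Low/NonLow label and
#' the mean SpO2 over the span.
#'
#' @param record A `subject_record`.
#' @param mask Per-sample validity from [screen_quality()]; `NULL` treats
#'   all samples as valid.
#' @param window_len,overlap Window length and overlap in seconds
#'   (`window_len > overlap >= 0`).
#' @param threshold CI class threshold passed to [label_window()].
#' @param filter_band,filter_order Band edges (Hz) and order for
#'   [bandpass_filter()].
#' @return List of `analysis_window` objects (possibly empty). The counts
#'   of windows dropped per rule are attached as attribute `"dropped"`.
#' @export
segment_windows <- function(record, mask = NULL, window_len = 60,
                            overlap = 10, threshold = 2.0,
                            filter_band = c(0.1, 15), filter_order = 2) {
  if (!(window_len > overlap && overlap >= 0))
    ppgci_error("ppgci_parameter_error",
                "need window_len > overlap >= 0")
  x <- record$ppg$values
  rate <- record$ppg$rate
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (length(mask) != length(x))
    ppgci_error("ppgci_parameter_error",
                "`mask` must match the PPG channel length")
  hop <- window_len - overlap
  n_win_samp <- round(window_len * rate)
  duration <- length(x) / rate
  dropped <- c(quality = 0L, no_ci = 0L)
  windows <- list()
  starts <- if (duration < window_len) numeric(0) else
    seq(0, duration - window_len, by = hop)
  for (s0 in starts) {
    i0 <- round(s0 * rate) + 1L
    idx <- i0:(i0 + n_win_samp - 1L)
    if (!all(mask[idx])) {
      dropped[["quality"]] <- dropped[["quality"]] + 1L
      next
    }
    ref <- tryCatch(assign_reference_ci(s0, s0 + window_len, record$ci),
                    ppgci_missing_reference = function(e) NULL)
    if (is.null(ref)) {
      dropped[["no_ci"]] <- dropped[["no_ci"]] + 1L
      next
    }
    raw <- x[idx]
    filt <- detrend_signal(bandpass_filter(raw, rate, filter_band[1L],
                                           filter_band[2L], filter_order))
    spo2_mean <- NA_real_
    if (!is.null(record$spo2)) {
      sel <- record$spo2$time >= s0 & record$spo2$time < s0 + window_len &
        is.finite(record$spo2$values)
      if (any(sel)) spo2_mean <- mean(record$spo2$values[sel])
    }
    windows[[length(windows) + 1L]] <- structure(
      list(subject_id = record$subject_id, start_time = s0,
           ppg_raw = raw, ppg_filtered = filt, rate = rate,
           reference_ci = ref, label = label_window(ref, threshold),
           spo2_mean = spo2_mean),
      class = "analysis_window")
  }
  attr(windows, "dropped") <- dropped
  windows
}
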