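# Beat detection, segmentation and ensemble averaging.

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# topographic prominence of each candidate peak
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(p - 1L)])
            else min(left)
    right <- x[(p + 1L):length(x)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
            else min(right)
    h - max(lmin, rmin)
  }, numeric(1L))
}

# robust beat-scale amplitude: median over 2-s blocks of (max - min)
median_peak_to_trough <- function(x, rate) {
  block <- max(2L, round(2 * rate))
  n_blk <- floor(length(x) / block)
  if (n_blk < 1L) return(diff(range(x)))
  amp <- vapply(seq_len(n_blk), function(b) {
    seg <- x[((b - 1L) * block + 1L):(b * block)]
    max(seg) - min(seg)
  }, numeric(1L))
  median(amp)
}

#' Detect systolic peaks in a filtered PPG window
#'
#' Local maxima with topographic prominence at least `prominence_frac`
#' times the median peak-to-trough amplitude of the window (measured as
#' the median over 2-s blocks of the block max minus min, a robust
#' estimate of the typical beat amplitude) and a minimum separation of
#' `min_separation` seconds (taller peaks win ties). The prominence rule
#' rejects both noise wiggles and dicrotic secondary peaks.
#'
#' @param x Band-passed, detrended PPG samples.
#' @param rate Sampling rate, Hz.
#' @param min_separation Minimum peak spacing, seconds.
#' @param prominence_frac Prominence threshold as a fraction of the median
#'   peak-to-trough amplitude.
#' @return Sorted integer sample indices (1-based). Fewer than 3 detected
#'   peaks raise an `ppgci_unanalyzable` error: the window cannot support
#'   a beat ensemble.
#' @export
detect_peaks <- function(x, rate, min_separation = 0.3,
                         prominence_frac = 0.3) {
  cand <- local_maxima(x)
  if (length(cand) < 3L)
    ppgci_error("ppgci_unanalyzable",
                "fewer than 3 candidate peaks in window")
  prom <- peak_prominence(x, cand)
  keep <- prom >= prominence_frac * median_peak_to_trough(x, rate)
  cand <- cand[keep]; prom <- prom[keep]
  # enforce separation, tallest first
  ord <- order(-x[cand])
  sel <- logical(length(cand))
  min_gap <- round(min_separation * rate)
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(cand[j] - taken) >= min_gap)) {
      sel[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  peaks <- sort(cand[sel])
  if (length(peaks) < 3L)
    ppgci_error("ppgci_unanalyzable", "fewer than 3 peaks in window")
  peaks
}

#' Segment a window into foot-to-foot beats
#'
#' The foot between two successive peaks is the sample of minimum
#' amplitude; beats are delimited foot-to-foot, so the first and last
#' (partial) beats are discarded. `N` peaks yield at most `N - 1` beats.
#'
#' @param x Filtered PPG samples.
#' @param peaks Peak indices from [detect_peaks()] (>= 3).
#' @return List of numeric beat segments, each starting at its foot.
#' @export
extract_beats <- function(x, peaks) {
  if (length(peaks) < 3L)
    ppgci_error("ppgci_unanalyzable", "need at least 3 peaks")
  feet <- vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- peaks[i]:peaks[i + 1L]
    span[which.min(x[span])]
  }, integer(1L))
  lapply(seq_len(length(feet) - 1L),
         function(i) x[feet[i]:(feet[i + 1L] - 1L)])
}

#' Average beats into a representative waveform
#'
#' Beats whose length deviates more than `length_tol` (fraction) from the
#' median beat length are excluded; the remainder are linearly
#' time-normalized to the median beat length and averaged pointwise.
#' Time-normalization prevents heart-rate variability from smearing the
#' dicrotic notch; the mean period is retained so duration features are
#' not lost. First/second derivatives are central differences scaled by
#' the sample interval.
#'
#' @param beats List of beat segments from [extract_beats()].
#' @param rate Sampling rate, Hz.
#' @param length_tol Relative beat-length exclusion tolerance.
#' @return An object of class `representative_beat` with fields `samples`,
#'   `beat_count`, `mean_period` (s), `d1`, `d2` and `rate`.
#' @export
average_beats <- function(beats, rate, length_tol = 0.4) {
  if (length(beats) < 3L)
    ppgci_error("ppgci_unanalyzable", "need at least 3 beats to average")
  lens <- lengths(beats)
  med <- median(lens)
  keep <- abs(lens - med) <= length_tol * med
  beats <- beats[keep]
  if (length(beats) < 3L)
    ppgci_error("ppgci_unanalyzable",
                "fewer than 3 beats of consistent length")
  target_len <- as.integer(round(median(lengths(beats))))
  xout <- seq(0, 1, length.out = target_len)
  norm <- vapply(beats, function(b) {
    approx(seq(0, 1, length.out = length(b)), b, xout = xout)$y
  }, numeric(target_len))
  samples <- rowMeans(norm)
  structure(
    list(samples = samples,
         beat_count = length(beats),
         mean_period = target_len / rate,
         d1 = central_diff(samples, 1 / rate, order = 1L),
         d2 = central_diff(samples, 1 / rate, order = 2L),
         rate = rate),
    class = "representative_beat")
}

# central differences with one-sided ends; same length as input
central_diff <- function(x, dt, order = 1L) {
  n <- length(x)
  if (order == 1L) {
    d <- numeric(n)
    d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
    d[1L] <- (x[2L] - x[1L]) / dt
    d[n] <- (x[n] - x[n - 1L]) / dt
    d
  } else {
    d <- numeric(n)
    d[2:(n - 1L)] <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) / dt^2
    d[1L] <- d[2L]
    d[n] <- d[n - 1L]
    d
  }
}

#' Build the representative beat of one analysis window
#'
#' Convenience chain of [detect_peaks()], [extract_beats()] and
#' [average_beats()].
#'
#' @param window An `analysis_window` from [segment_windows()].
#' @inheritParams detect_peaks
#' @return A `representative_beat`.
#' @export
representative_beat <- function(window, min_separation = 0.3,
                                prominence_frac = 0.3) {
  peaks <- detect_peaks(window$ppg_filtered, window$rate,
                        min_separation, prominence_frac)
  beats <- extract_beats(window$ppg_filtered, peaks)
  average_beats(beats, window$rate)
}
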