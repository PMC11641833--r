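# Fiducial point detection and the twenty pulse-wave features.

#' Names of the twenty pulse-wave features, in canonical order
#'
#' @format Character vector of length 20.
#' @export
ppg_feature_names <- c(
  "dPoint", "plethPerf", "diff2Quant25", "plethHr", "Ta1", "Featb2",
  "diff2SpecEntropy", "diff2IQR", "diff1SpecEntropy", "c1", "tpt",
  "plethSkewness", "plethKurtosis", "plethSat", "systPeak",
  "plethPeakRms", "plethSpecEntropy", "fftMean", "areaTotal", "area2")

#' Detect fiducial points on a representative beat
#'
#' Beats are foot-aligned, so the foot is the first sample. The systolic
#' peak is the global maximum; `a1` is the first local maximum of the
#' first derivative before the systolic peak (the steepest upstroke);
#' `b2` is the global minimum of the second derivative; `c1` is the first
#' local maximum of the second derivative strictly after the systolic
#' peak. The dicrotic notch is the first local minimum of the beat after
#' the systolic peak; if the beat has no such minimum (a notch-free,
#' single-lobe beat), the fallback is the sample after `c1` where the
#' first derivative is closest to zero.
#'
#' @param beat A `representative_beat` from [average_beats()].
#' @return List of 1-based indices: `foot_idx`, `a1_idx`,
#'   `systolic_peak_idx`, `dicrotic_notch_idx`, `b2_idx`, `c1_idx`.
#' @export
detect_fiducials <- function(beat) {
  s <- beat$samples; d1 <- beat$d1; d2 <- beat$d2
  n <- length(s)
  syst <- which.max(s)
  if (syst <= 1L || syst >= n)
    ppgci_error("ppgci_fiducial_error",
                "beat is monotone; no systolic structure")
  foot <- 1L

  pre <- seq_len(syst - 1L)
  a1_cand <- local_maxima(d1[pre])
  a1 <- if (length(a1_cand)) a1_cand[1L] else which.max(d1[pre])
  a1 <- max(a1, 2L)

  b2 <- which.min(d2)

  post <- (syst + 1L):n
  c1_cand <- local_maxima(d2[post])
  c1 <- if (length(c1_cand)) syst + c1_cand[1L]
        else syst + which.max(d2[post])

  notch_cand <- local_minima(s[post])
  if (length(notch_cand)) {
    notch <- syst + notch_cand[1L]
  } else {
    after <- c1:n
    notch <- after[which.min(abs(d1[after]))]
  }

  fid <- list(foot_idx = foot, a1_idx = a1, systolic_peak_idx = syst,
              dicrotic_notch_idx = notch, b2_idx = b2, c1_idx = c1)
  if (!(foot < a1 && a1 < syst && syst < notch && notch <= n))
    ppgci_error("ppgci_fiducial_error",
                "fiducial ordering violated; beat rejected")
  fid
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n]) + 1L
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the power-spectrum mass function: a Hann-windowed
#' periodogram is normalized to sum one (DC bin excluded) and the entropy
#' is divided by the log of the number of retained bins, giving a value in
#' \[0, 1\] -- near 0 for a pure tone, near 1 for white noise.
#'
#' @param x Samples (>= 16).
#' @param rate Sampling rate, Hz (retained for interface symmetry; the
#'   normalized entropy does not depend on it).
#' @return Spectral entropy in \[0, 1\].
#' @export
spectral_entropy <- function(x, rate = 125) {
  n <- length(x)
  if (n < 16L)
    ppgci_error("ppgci_input_error",
                "spectral entropy needs at least 16 samples")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- fft((x - mean(x)) * w)
  p <- Mod(X[2:(floor(n / 2) + 1L)])^2
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(floor(n / 2))
}

#' Compute the twenty pulse-wave features for one window
#'
#' Feature conventions (the published table gives descriptions, not
#' formulas; these are the package's declared definitions):
#' \describe{
#'   \item{dPoint}{Beat value at the dicrotic notch minus the foot value.}
#'   \item{plethPerf}{Perfusion index proxy on the *raw* window (the DC
#'     level is destroyed by detrending): (95th - 5th percentile) divided
#'     by the median level.}
#'   \item{diff2Quant25, diff2IQR}{25th percentile and interquartile range
#'     of the representative beat's second derivative
#'     (linear-interpolation quantiles).}
#'   \item{plethHr}{60 / mean beat period, beats/min.}
#'   \item{Ta1}{Time from the foot to the first maximum of the first
#'     derivative, seconds.}
#'   \item{Featb2}{Signed minimum of the second derivative.}
#'   \item{c1}{Second-derivative value at its first local maximum after
#'     the systolic peak.}
#'   \item{tpt}{Total beat time span = mean period, seconds.}
#'   \item{plethSkewness, plethKurtosis}{Sample skewness and (Pearson,
#'     normal = 3) kurtosis of the beat amplitude distribution.}
#'   \item{plethSat}{Mean SpO2 numeric value over the window; a
#'     single-wavelength PPG cannot yield saturation, so the monitor
#'     numeric is treated as an auxiliary input channel.}
#'   \item{systPeak}{Systolic peak value minus the foot value.}
#'   \item{plethPeakRms}{max|beat - mean| / RMS(beat - mean).}
#'   \item{plethSpecEntropy, diff1SpecEntropy, diff2SpecEntropy}{
#'     [spectral_entropy()] of the filtered window signal and of the
#'     representative beat's first / second derivatives.}
#'   \item{fftMean}{Mean magnitude of the one-sided FFT of the beat, DC
#'     excluded.}
#'   \item{areaTotal, area2}{Trapezoidal area (s x PPG units) under the
#'     foot-referenced beat, clamped at zero, over the full beat and from
#'     systolic peak to dicrotic notch respectively.}
#' }
#'
#' @param window An `analysis_window`.
#' @param beat Its `representative_beat`.
#' @param fid Its fiducial set from [detect_fiducials()].
#' @return Named numeric vector of length 20 in [ppg_feature_names] order.
#' @export
compute_features <- function(window, beat, fid) {
  s <- beat$samples; d1 <- beat$d1; d2 <- beat$d2
  rate <- beat$rate
  foot_val <- s[fid$foot_idx]
  sc <- s - mean(s)
  ref <- pmax(s - foot_val, 0)
  dt <- 1 / rate
  n <- length(s)
  fft_mag <- Mod(fft(s))[2:(floor(n / 2) + 1L)]

  f <- c(
    dPoint = s[fid$dicrotic_notch_idx] - foot_val,
    plethPerf = as.numeric(
      (quantile(window$ppg_raw, 0.95) - quantile(window$ppg_raw, 0.05)) /
        median(window$ppg_raw)),
    diff2Quant25 = as.numeric(quantile(d2, 0.25)),
    plethHr = 60 / beat$mean_period,
    Ta1 = (fid$a1_idx - fid$foot_idx) / rate,
    Featb2 = d2[fid$b2_idx],
    diff2SpecEntropy = spectral_entropy(d2, rate),
    diff2IQR = IQR(d2),
    diff1SpecEntropy = spectral_entropy(d1, rate),
    c1 = d2[fid$c1_idx],
    tpt = beat$mean_period,
    plethSkewness = e1071::skewness(s, type = 1),
    plethKurtosis = e1071::kurtosis(s, type = 1) + 3,
    plethSat = window$spo2_mean,
    systPeak = s[fid$systolic_peak_idx] - foot_val,
    plethPeakRms = max(abs(sc)) / sqrt(mean(sc^2)),
    plethSpecEntropy = spectral_entropy(window$ppg_filtered, rate),
    fftMean = mean(fft_mag),
    areaTotal = trapz_dt(ref, dt),
    area2 = trapz_dt(ref[fid$systolic_peak_idx:fid$dicrotic_notch_idx], dt)
  )
  f <- f[ppg_feature_names]
  bad <- names(f)[!is.finite(f)]
  if (length(bad))
    ppgci_error("ppgci_feature_error",
                paste("non-finite feature:", paste(bad, collapse = ", ")))
  if (f[["tpt"]] <= 0 || f[["plethHr"]] <= 20 || f[["plethHr"]] >= 250)
    ppgci_error("ppgci_feature_error", "implausible beat period")
  f
}

#' Build the window-by-feature table for a set of records
#'
#' Runs quality screening, windowing, beat averaging, fiducial detection
#' and feature computation for every record, dropping unanalyzable
#' windows with a logged reason. Rows are ordered by (subject,
#' start_time).
#'
#' @param records List of `subject_record` objects.
#' @param threshold CI class threshold (L/min/m^2).
#' @param window_len,overlap Windowing parameters in seconds.
#' @param quality Apply [screen_quality()] (`TRUE`) or accept all samples.
#' @return `data.frame` with the twenty feature columns (fixed order),
#'   then `label`, `reference_ci`, `subject_id`, `start_time`. Dropped
#'   windows are recorded in attribute `"dropped"` as a data.frame with
#'   columns subject, start_time, reason.
#' @export
build_feature_table <- function(records, threshold = 2.0, window_len = 60,
                                overlap = 10, quality = TRUE) {
  rows <- list()
  drops <- list()
  for (rec in records) {
    mask <- if (quality) screen_quality(rec) else NULL
    wins <- segment_windows(rec, mask, window_len, overlap, threshold)
    for (w in wins) {
      res <- tryCatch({
        beat <- representative_beat(w)
        fid <- detect_fiducials(beat)
        compute_features(w, beat, fid)
      }, ppgci_error = function(e) e)
      if (inherits(res, "ppgci_error")) {
        drops[[length(drops) + 1L]] <- data.frame(
          subject = w$subject_id, start_time = w$start_time,
          reason = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          t(res), label = w$label, reference_ci = w$reference_ci,
          subject_id = w$subject_id, start_time = w$start_time)
      }
    }
  }
  if (!length(rows))
    ppgci_error("ppgci_input_error", "no analyzable windows")
  ft <- do.call(rbind, rows)
  ft <- ft[order(ft$subject_id, ft$start_time), , drop = FALSE]
  rownames(ft) <- NULL
  attr(ft, "dropped") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(subject = character(0), start_time = numeric(0),
               reason = character(0))
  ft
}
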