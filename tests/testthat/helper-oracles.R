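# Independent oracles and fixture builders used across the test files.
# These re-derive expected values from first principles and share no code
# with the implementation paths they check.

# --- dense-grid analysis of the two-Gaussian beat model ------------------
# Evaluates the closed-form mixture on a fine grid, rotates it to start at
# the waveform foot (the global minimum, which is where the beat
# segmentation cuts), and locates every landmark by direct search.
# Positions are returned as expected 1-based sample indices at `rate`.
oracle_beat_landmarks <- function(tpl, period, rate, n_dense = 100000L) {
  mix <- function(fr) {
    wrap <- function(d) {
      dd <- abs(d) %% 1
      pmin(dd, 1 - dd)
    }
    exp(-0.5 * (wrap(fr - tpl$systolic_time_frac) /
                  tpl$pulse_widths[1])^2) +
      tpl$dicrotic_gain *
        exp(-0.5 * (wrap(fr - tpl$dicrotic_time_frac) /
                      tpl$pulse_widths[2])^2)
  }
  f <- (seq_len(n_dense) - 1) / n_dense
  # the pipeline cuts beats at the argmin of the 125-Hz samples; in a flat
  # inter-beat valley that differs from the dense argmin, so the oracle
  # applies the same sampling convention to locate the foot
  n_samp0 <- round(period * rate)
  fs <- (seq_len(n_samp0) - 1) / n_samp0
  foot_phase <- fs[which.min(mix(fs))]
  s <- mix(foot_phase + f)
  d1 <- c(s[2] - s[1], (s[3:n_dense] - s[1:(n_dense - 2)]) / 2,
          s[n_dense] - s[n_dense - 1])
  d2 <- c(0, s[3:n_dense] - 2 * s[2:(n_dense - 1)] + s[1:(n_dense - 2)], 0)
  first_lmax <- function(v, from = 2L, to = length(v) - 1L) {
    for (i in seq(from, to)) {
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) return(i)
    }
    NA_integer_
  }
  first_lmin <- function(v, from, to = length(v) - 1L) {
    for (i in seq(from, to)) {
      if (v[i] < v[i - 1] && v[i] <= v[i + 1]) return(i)
    }
    NA_integer_
  }
  pk <- which.max(s)
  notch <- first_lmin(s, from = pk + 1L)
  a1 <- first_lmax(d1, to = pk)
  b2 <- which.min(d2)
  c1p <- first_lmax(d2, from = pk + 1L)
  n_samp <- round(period * rate)
  to_idx <- function(i) {
    if (is.na(i)) return(NA_integer_)
    round((i - 1) / n_dense * n_samp) + 1L
  }
  peak_val <- s[pk]
  notch_val <- if (is.na(notch)) NA_real_ else s[notch]
  foot_val <- min(s)
  list(systolic_peak_idx = to_idx(pk),
       dicrotic_notch_idx = to_idx(notch),
       a1_idx = to_idx(a1), b2_idx = to_idx(b2), c1_idx = to_idx(c1p),
       notch_ratio = (notch_val - foot_val) / (peak_val - foot_val))
}

# --- brute-force RReliefF ------------------------------------------------
# Literal nested-loop transcription of the running-weight updates and the
# final predictor-weight formula, exhaustive over observations.
oracle_relief <- function(X, y, k, sigma = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  scale01 <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  Xs <- apply(X, 2L, scale01)
  ys <- scale01(y)
  dq <- exp(-((1:k) / sigma)^2)
  dq <- dq / sum(dq)
  W_dy <- 0
  W_dj <- rep(0, p)
  W_dydj <- rep(0, p)
  for (r in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (q in seq_len(n)) {
      if (q != r) d[q] <- sum(abs(Xs[q, ] - Xs[r, ]))
    }
    nb <- order(d, seq_len(n), na.last = TRUE)[1:k]
    for (ii in seq_len(k)) {
      q <- nb[ii]
      dy <- abs(ys[q] - ys[r])
      W_dy <- W_dy + dy * dq[ii]
      for (j in seq_len(p)) {
        dj <- abs(Xs[q, j] - Xs[r, j])
        W_dj[j] <- W_dj[j] + dj * dq[ii]
        W_dydj[j] <- W_dydj[j] + dy * dj * dq[ii]
      }
    }
  }
  W_dydj / W_dy - (W_dj - W_dydj) / (n - W_dy)
}

# --- fixture builders ----------------------------------------------------
make_window <- function(filtered, rate = 125, raw = NULL, ci = 2.3,
                        spo2 = 98) {
  structure(
    list(subject_id = "T01", start_time = 0,
         ppg_raw = if (is.null(raw)) filtered + 2 else raw,
         ppg_filtered = filtered, rate = rate,
         reference_ci = ci, label = label_window(ci), spo2_mean = spo2),
    class = "analysis_window")
}

# clean repeated-template pulse train of `n_beats` beats
make_pulse_train <- function(tpl = beat_template_params(), period = 0.8,
                             rate = 125, n_beats = 75) {
  rep(simulate_beat(tpl, period, rate), n_beats)
}

# feature table with one informative column and noise elsewhere
make_sep_table <- function(n = 200, effect = 3, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    label <- factor(rep(c("Low", "NonLow"), length.out = n),
                    levels = c("Low", "NonLow"))
    ft <- as.data.frame(matrix(rnorm(n * 20), n, 20,
                               dimnames = list(NULL, ppg_feature_names)))
    ft$systPeak <- ifelse(label == "Low", 0, effect) + rnorm(n, 0, sd)
    ft$label <- label
    ft$reference_ci <- ifelse(label == "Low", 1.7, 2.4) + rnorm(n, 0, 0.1)
    ft$subject_id <- sprintf("S%02d", rep(1:10, length.out = n))
    ft$start_time <- seq_len(n)
    ft
  })
}
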