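# Relief predictor weighting for a continuous response (RReliefF).
#
# Per iteration an observation x_r is selected and its k nearest
# neighbors x_q found (Manhattan distance on range-scaled predictors).
# Three running weights accumulate over iterations i:
#
#   W_dy    <- W_dy    + Dy(x_r, x_q) * d_qr
#   W_dj    <- W_dj    + Dj(x_r, x_q) * d_qr
#   W_dy&dj <- W_dy&dj + Dy(x_r, x_q) * Dj(x_r, x_q) * d_qr
#
# and after m iterations each predictor's weight is
#
#   W_j = W_dy&dj / W_dy - (W_dj - W_dy&dj) / (m - W_dy).
#
# Dy and Dj are absolute differences scaled by the observed range of the
# response / predictor; d_qr are rank-based neighbor weights normalized
# to sum one over the k neighbors of one observation.

#' Relief predictor weights for a continuous response
#'
#' @param X Numeric matrix or data.frame of predictors (rows =
#'   observations). Predictors are internally scaled to \[0, 1\] by their
#'   observed range; constant predictors contribute zero difference and
#'   receive weight exactly 0.
#' @param y Numeric response (continuous; a binary factor is coerced to
#'   0/1, making the response difference an indicator of class
#'   disagreement).
#' @param k Number of nearest neighbors (default 10; `k < n` required).
#' @param m Number of iterations for random selection mode. Ignored when
#'   `exhaustive = TRUE` (the default), which iterates every observation
#'   once in order — fully deterministic without a seed.
#' @param exhaustive Iterate all observations (`TRUE`) or sample `m`
#'   observations with replacement using `seed`.
#' @param seed Integer seed for random selection mode.
#' @param neighbor_weighting `"exp"` for exponentially decaying rank
#'   weights `exp(-(rank/sigma)^2)` (normalized to sum 1), `"uniform"`
#'   for 1/k.
#' @param sigma Decay scale of the exponential rank weights.
#' @return An object of class `relief_result`: `weights` (named, one per
#'   predictor), `ranking` (predictor names by decreasing weight, ties
#'   broken by column order), the running sums `W_dy`, `W_dj`, `W_dydj`,
#'   and `m`.
#' @examples
#' set.seed(1)
#' X <- cbind(signal = runif(60), noise = runif(60))
#' y <- X[, "signal"] + rnorm(60, 0, 0.05)
#' r <- relief_weights(X, y)
#' r$ranking[1] # "signal"
#' @export
relief_weights <- function(X, y, k = 10L, m = NULL, exhaustive = TRUE,
                           seed = NULL,
                           neighbor_weighting = c("exp", "uniform"),
                           sigma = 50) {
  neighbor_weighting <- match.arg(neighbor_weighting)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (is.factor(y) || is.logical(y) || is.character(y)) {
    y <- as.numeric(factor(y)) - 1
  }
  if (length(y) != n)
    ppgci_error("ppgci_parameter_error", "`y` must match nrow(X)")
  if (k < 1L || k >= n)
    ppgci_error("ppgci_parameter_error",
                sprintf("`k` = %d must satisfy 1 <= k < n = %d", k, n))
  ry <- diff(range(y))
  if (ry == 0)
    ppgci_error("ppgci_degenerate_response", paste(
      "degenerate response: all response values are equal, so the",
      "response-difference weight W_dy is 0 and the final weight",
      "W_j = W_dy&dj/W_dy - ... divides by zero"))

  rngs <- apply(X, 2L, function(col) diff(range(col)))
  Xs <- X
  for (j in seq_len(p))
    Xs[, j] <- if (rngs[j] > 0) (X[, j] - min(X[, j])) / rngs[j] else 0
  ys <- (y - min(y)) / ry

  D <- as.matrix(stats::dist(Xs, method = "manhattan"))

  idx <- if (exhaustive) seq_len(n) else {
    if (is.null(m)) m <- n
    if (is.null(seed))
      ppgci_error("ppgci_parameter_error",
                  "random selection mode requires a `seed`")
    with_seed(seed, sample.int(n, m, replace = TRUE))
  }
  m_used <- length(idx)

  dq <- if (neighbor_weighting == "exp") {
    w <- exp(-((seq_len(k)) / sigma)^2); w / sum(w)
  } else rep(1 / k, k)

  W_dy <- 0
  W_dj <- numeric(p)
  W_dydj <- numeric(p)
  for (r in idx) {
    o <- order(D[r, ], seq_len(n))
    nb <- o[o != r][seq_len(k)]
    dy <- abs(ys[nb] - ys[r])                 # k-vector
    dj <- abs(Xs[nb, , drop = FALSE] -
                matrix(Xs[r, ], k, p, byrow = TRUE))  # k x p
    W_dy <- W_dy + sum(dy * dq)
    W_dj <- W_dj + colSums(dj * dq)
    W_dydj <- W_dydj + colSums(dj * (dy * dq))
  }
  if (W_dy == 0)
    ppgci_error("ppgci_degenerate_response",
                "degenerate response: W_dy accumulated to 0")
  W <- W_dydj / W_dy - (W_dj - W_dydj) / (m_used - W_dy)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("V", seq_len(p))
  names(W) <- nms
  structure(
    list(weights = W,
         ranking = nms[order(-W, seq_len(p))],
         W_dy = W_dy, W_dj = setNames(W_dj, nms),
         W_dydj = setNames(W_dydj, nms),
         m = m_used, k = k,
         neighbor_weighting = neighbor_weighting, sigma = sigma),
    class = "relief_result")
}

#' Select the top-weighted predictors
#'
#' @param result A `relief_result`.
#' @param n_keep Number of predictors to keep (ties broken by column
#'   order, which is already encoded in `result$ranking`).
#' @return Character vector of predictor names.
#' @export
select_top <- function(result, n_keep = 20L) {
  if (!inherits(result, "relief_result"))
    ppgci_error("ppgci_parameter_error", "`result` must be a relief_result")
  if (n_keep > length(result$ranking))
    ppgci_error("ppgci_parameter_error",
                "`n_keep` exceeds the number of predictors")
  result$ranking[seq_len(n_keep)]
}

#' @export
print.relief_result <- function(x, ...) {
  cat(sprintf("<relief_result>  %d predictors, m = %d, k = %d\n",
              length(x$weights), x$m, x$k))
  print(round(sort(x$weights, decreasing = TRUE), 5))
  invisible(x)
}
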