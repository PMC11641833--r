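# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# classed conditions so the pipeline can distinguish drop reasons from bugs
ppgci_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ppgci_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ppgci_error("ppgci_parameter_error",
                sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    ppgci_error("ppgci_parameter_error",
                sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

trapz_dt <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * sum((y[-1] + y[-n]) / 2)
}

gcd2 <- function(a, b) if (b == 0L) a else Recall(b, a %% b)

# express target_rate/src_rate as a reduced integer ratio p/q
rate_ratio <- function(src_rate, target_rate, max_denom = 1e6) {
  scale <- 1L
  while (scale < max_denom &&
         (abs(src_rate * scale - round(src_rate * scale)) > 1e-9 ||
          abs(target_rate * scale - round(target_rate * scale)) > 1e-9)) {
    scale <- scale * 10L
  }
  p <- as.integer(round(target_rate * scale))
  q <- as.integer(round(src_rate * scale))
  if (p <= 0L || q <= 0L)
    ppgci_error("ppgci_parameter_error", "rates must be positive")
  d <- gcd2(p, q)
  c(p = p %/% d, q = q %/% d)
}
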