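# Plain-text subject-record format and channel resampling.
#
# Record files are self-describing column text, one file per subject:
#
#   #ppgrec 1
#   #subject S001
#   #meta age=67 sex=M height=165 weight=67.1
#   #channel name=ppg rate=125 n=75000
#   #channel name=ci rate=0.5 n=300
#   @ppg
#   <n samples, one per line, full precision; missing samples written "NA">
#   @ci
#   ...
#
# Samples are time-implicit: sample k of a channel lies at (k-1)/rate
# seconds from the shared time origin.

#' Write a subject record to a plain-text file
#'
#' @param record A `subject_record` (see [simulate_subject()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  if (!inherits(record, "subject_record"))
    ppgci_error("ppgci_parameter_error",
                "`record` must be a `subject_record`")
  chans <- c("ppg", "ci", "spo2")
  chans <- chans[!vapply(record[chans], is.null, logical(1L))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#ppgrec 1", con)
  writeLines(paste("#subject", record$subject_id), con)
  meta <- record$meta
  writeLines(paste("#meta", paste(sprintf("%s=%s", names(meta),
                                          vapply(meta, format, "")),
                                  collapse = " ")), con)
  for (ch in chans)
    writeLines(sprintf("#channel name=%s rate=%s n=%d", ch,
                       format(record[[ch]]$rate, digits = 17),
                       length(record[[ch]]$values)), con)
  for (ch in chans) {
    writeLines(paste0("@", ch), con)
    v <- record[[ch]]$values
    out <- ifelse(is.finite(v), formatC(v, digits = 17, format = "g"), "NA")
    writeLines(out, con)
  }
  invisible(path)
}

format_error <- function(line, msg) {
  ppgci_error("ppgci_format_error", sprintf("line %d: %s", line, msg))
}

#' Read a subject record from a plain-text file
#'
#' Missing-sample sentinels (`NA`) become `NA` values in the channel; the
#' per-sample gap mask is recoverable as `!is.finite(values)`.
#'
#' @param path Path to a record file written by [write_record()].
#' @return A `subject_record`.
#' @export
read_record <- function(path) {
  if (!file.exists(path))
    ppgci_error("ppgci_format_error", paste("no such file:", path))
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#ppgrec"))
    format_error(1L, "missing `#ppgrec` signature")
  subject_id <- NULL
  meta <- list()
  chan_info <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    ln <- lines[i]
    if (startsWith(ln, "#subject ")) {
      subject_id <- sub("^#subject +", "", ln)
    } else if (startsWith(ln, "#meta")) {
      kv <- strsplit(trimws(sub("^#meta *", "", ln)), " +")[[1L]]
      kv <- kv[nzchar(kv)]
      for (pair in strsplit(kv, "=")) {
        val <- suppressWarnings(as.numeric(pair[2L]))
        meta[[pair[1L]]] <- if (is.na(val)) pair[2L] else val
      }
    } else if (startsWith(ln, "#channel ")) {
      fields <- strsplit(trimws(sub("^#channel +", "", ln)), " +")[[1L]]
      kv <- strsplit(fields, "=")
      vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
      if (!all(c("name", "rate", "n") %in% names(vals)))
        format_error(i, "channel header needs name=, rate=, n=")
      rate <- as.numeric(vals[["rate"]])
      n <- as.integer(vals[["n"]])
      if (!is.finite(rate) || rate <= 0)
        format_error(i, "channel rate must be a positive number")
      if (is.na(n) || n <= 0L)
        format_error(i, "channel must declare a positive sample count")
      chan_info[[vals[["name"]]]] <- list(rate = rate, n = n, header_line = i)
    }
    i <- i + 1L
  }
  if (is.null(subject_id)) format_error(1L, "missing `#subject` header")
  if (!length(chan_info)) format_error(1L, "no `#channel` headers")

  channels <- list()
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "@"))
      format_error(i, "expected a `@channel` block marker")
    nm <- sub("^@", "", lines[i])
    if (is.null(chan_info[[nm]]))
      format_error(i, sprintf("block `@%s` has no channel header", nm))
    n <- chan_info[[nm]]$n
    if (i + n > length(lines))
      format_error(i, sprintf(
        "channel `%s` declares %d samples but the file ends early", nm, n))
    raw <- lines[(i + 1L):(i + n)]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & raw != "NA")
    if (length(bad))
      format_error(i + bad[1L], sprintf("unparseable sample %s", raw[bad[1L]]))
    rate <- chan_info[[nm]]$rate
    channels[[nm]] <- list(
      time = (seq_len(n) - 1) / rate, values = v, rate = rate)
    i <- i + n + 1L
  }
  missing_blocks <- setdiff(names(chan_info), names(channels))
  if (length(missing_blocks))
    format_error(length(lines), paste("missing data block for channel",
                                      missing_blocks[1L]))
  if (is.null(channels$ppg))
    format_error(1L, "record has no `ppg` channel")
  channels$ppg$time <- NULL
  structure(
    list(subject_id = subject_id,
         ppg = channels$ppg, ci = channels$ci, spo2 = channels$spo2,
         meta = meta),
    class = "subject_record")
}

#' Resample a channel to a target rate
#'
#' Two methods: `"fir"` performs polyphase low-pass resampling (Kaiser
#' windowed-sinc FIR, reflection padding, integer group-delay
#' compensation) and is the default for waveform channels; `"step"` uses
#' previous-value (zero-order-hold) interpolation, the appropriate choice
#' for the thermodilution CI channel, whose values are 60-s-cadence
#' measurements -- intermediate physiology must not be invented between
#' updates.
#'
#' @param values Numeric sample vector (no gaps for `"fir"`).
#' @param src_rate,target_rate Source and target rates in Hz.
#' @param method `"fir"` or `"step"`.
#' @return List with `values` and `rate`; the duration is preserved within
#'   one output sample (`ceiling(n * target_rate / src_rate)` samples).
#' @export
resample_channel <- function(values, src_rate, target_rate,
                             method = c("fir", "step")) {
  method <- match.arg(method)
  check_number(src_rate, "src_rate", lower = 0, strict_lower = TRUE)
  check_number(target_rate, "target_rate", lower = 0, strict_lower = TRUE)
  if (anyNA(values) && method == "fir")
    ppgci_error("ppgci_gap_error",
                "channel contains gaps; fill or mask them before FIR resampling")
  pq <- rate_ratio(src_rate, target_rate)
  p <- pq[["p"]]; q <- pq[["q"]]
  if (p == q) return(list(values = values, rate = target_rate))
  n <- length(values)
  n_out <- as.integer(ceiling(n * p / q))
  if (method == "step") {
    src_idx <- pmin(floor((seq_len(n_out) - 1) * q / p) + 1L, n)
    return(list(values = values[src_idx], rate = target_rate))
  }
  list(values = polyphase_resample(values, p, q), rate = target_rate)
}

# Kaiser windowed-sinc polyphase resampler; returns ceiling(n*p/q) samples
polyphase_resample <- function(x, p, q, half_mult = 40L, beta = 12) {
  n <- length(x)
  if (n < 4L)
    ppgci_error("ppgci_input_error", "too few samples to resample")
  N <- half_mult * max(p, q)
  fc <- 1 / max(p, q)
  h <- signal::fir1(2L * N, fc,
                    window = signal::kaiser(2L * N + 1L, beta)) * p
  pad <- min(ceiling(N / p) + 1L, n - 1L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  up <- numeric(length(xp) * p)
  up[seq(1L, length(up), by = p)] <- xp
  yf <- as.numeric(stats::filter(up, h, sides = 1))
  n_out <- as.integer(ceiling(n * p / q))
  yf[(0:(n_out - 1L)) * q + pad * p + N + 1L]
}

#' Write / read a feature table as CSV
#'
#' One row per analysis window; columns are the twenty features (see
#' [ppg_feature_names]) followed by `label`, `reference_ci`, `subject_id`
#' and `start_time`.
#'
#' @param table A feature table (see [build_feature_table()]).
#' @param path CSV file path.
#' @return `path` invisibly; for the reader, the feature table.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ppg_feature_names, names(ft))
  if (length(missing))
    ppgci_error("ppgci_format_error",
                paste("feature table is missing columns:",
                      paste(missing, collapse = ", ")))
  ft$label <- factor(ft$label, levels = c("Low", "NonLow"))
  ft
}
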