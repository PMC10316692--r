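#' Construct a raw signal read
#'
#' @param read_id Read identifier.
#' @param samples Numeric vector of raw current samples (instrument units).
#' @param sample_rate Sampling rate in Hz (informational; default 4000).
#' @param meta Optional named list of channel metadata.
#' @return An object of class `raw_read`.
#' @export
raw_read <- function(read_id, samples, sample_rate = 4000, meta = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0 || !all(is.finite(samples))) {
    sqm_stop("raw read samples must be non-empty and finite",
             "sqm_domain_error")
  }
  structure(list(read_id = as.character(read_id), samples = samples,
                 sample_rate = sample_rate, meta = meta),
            class = "raw_read")
}

#' @export
print.raw_read <- function(x, ...) {
  cat(sprintf("<raw_read> '%s': %d samples @ %g Hz\n",
              x$read_id, length(x$samples), x$sample_rate))
  invisible(x)
}

#' Read raw signal reads from disk
#'
#' Supports ASCII SLOW5 (header lines starting with `#` or `@`; data rows
#' carrying `read_id`, `len_raw_signal` and a comma-separated `raw_signal`
#' column) and a plain TSV fallback of
#' `read_id<TAB>comma-separated-samples` lines.  Binary BLOW5 is not
#' supported; convert to SLOW5 first.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"tsv"`, `"slow5"`.  `"auto"` picks by
#'   file extension (`.slow5` vs anything else).
#' @return List of [raw_read()] objects in file order.  Empty records are
#'   skipped with a warning and counted in attribute `n_skipped`.
#' @export
read_raw_reads <- function(path, format = c("auto", "tsv", "slow5", "blow5")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    sqm_stop(paste0("signal file not found: ", path), "sqm_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.slow5$", path)) "slow5"
              else if (grepl("\\.blow5$", path)) "blow5"
              else "tsv"
  }
  if (format == "blow5") {
    sqm_stop("binary BLOW5 is not supported; convert to ASCII SLOW5",
             "sqm_io_error")
  }
  if (format == "slow5") read_slow5(path) else read_reads_tsv(path)
}

read_reads_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  reads <- list()
  n_skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(trimws(parts[2]))) {
      warning(sprintf("skipping empty read record '%s'",
                      substr(ln, 1, 30)))
      n_skipped <- n_skipped + 1L
      next
    }
    samples <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    if (anyNA(samples)) {
      sqm_stop(sprintf("non-numeric samples for read '%s'", parts[1]),
               "sqm_format_error")
    }
    reads[[length(reads) + 1L]] <- raw_read(parts[1], samples)
  }
  structure(reads, n_skipped = n_skipped)
}

read_slow5 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_cols <- NULL
  reads <- list()
  n_skipped <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) next
    first <- substr(ln, 1, 1)
    if (first == "@") next
    if (first == "#") {
      f <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      if (f[1] == "read_id") hdr_cols <- f
      next
    }
    if (is.null(hdr_cols)) {
      sqm_stop("SLOW5 data row before '#read_id' column header",
               "sqm_format_error")
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- f[match("read_id", hdr_cols)]
    sig <- f[match("raw_signal", hdr_cols)]
    rate_i <- match("sampling_rate", hdr_cols)
    rate <- if (!is.na(rate_i)) as.numeric(f[rate_i]) else 4000
    if (is.na(sig) || !nzchar(sig) || sig == ".") {
      warning(sprintf("skipping SLOW5 record '%s' with empty signal", id))
      n_skipped <- n_skipped + 1L
      next
    }
    samples <- as.numeric(strsplit(sig, ",", fixed = TRUE)[[1]])
    reads[[length(reads) + 1L]] <- raw_read(id, samples, sample_rate = rate)
  }
  structure(reads, n_skipped = n_skipped)
}

#' Write reads as the plain-TSV raw signal format
#'
#' @param reads List of [raw_read()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  lines <- vapply(reads, function(r) {
    paste0(r$read_id, "\t", paste(format(r$samples, digits = 17,
                                         trim = TRUE, scientific = FALSE),
                                  collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as ASCII SLOW5
#'
#' Emits a minimal single-read-group SLOW5 file readable by
#' [read_raw_reads()].
#'
#' @inheritParams write_reads_tsv
#' @export
write_slow5 <- function(reads, path) {
  hdr <- c("#slow5_version\t0.2.0",
           "#num_read_groups\t1",
           "@asic_id\tsynthetic",
           paste("#char*", "uint32_t", "double", "double", "double", "double",
                 "uint64_t", "int16_t*", sep = "\t"),
           paste("#read_id", "read_group", "digitisation", "offset", "range",
                 "sampling_rate", "len_raw_signal", "raw_signal", sep = "\t"))
  rows <- vapply(reads, function(r) {
    paste(r$read_id, 0, 8192, 0, 1500, r$sample_rate, length(r$samples),
          paste(round(r$samples), collapse = ","), sep = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Event detection parameters
#'
#' Event segmentation uses two Welch-style sliding t-statistics computed on
#' window pairs straddling each candidate boundary: a short window that
#' localizes level changes sharply and a long window whose stringent
#' threshold confirms them.  A sample becomes an event boundary when the
#' short-window statistic is a local maximum exceeding `threshold_short`
#' with prominence at least `peak_height`, and the long-window statistic at
#' the same position exceeds `threshold_long`.
#'
#' @param window_short Short window length in samples (default 4).
#' @param window_long Long window length in samples (default 8).
#' @param threshold_short t-statistic threshold for the short window
#'   (default 1.4).
#' @param threshold_long t-statistic threshold for the long window
#'   (default 9.0).
#' @param peak_height Minimum prominence of a short-statistic peak over the
#'   surrounding minimum (default 0.2).
#' @return An object of class `event_detection_params`.
#' @export
event_detection_params <- function(window_short = 4L, window_long = 8L,
                                   threshold_short = 1.4,
                                   threshold_long = 9.0,
                                   peak_height = 0.2) {
  if (!(window_short < window_long)) {
    sqm_stop("`window_short` must be smaller than `window_long`",
             "sqm_config_error")
  }
  if (threshold_short <= 0 || threshold_long <= 0) {
    sqm_stop("thresholds must be positive", "sqm_config_error")
  }
  structure(list(window_short = as.integer(window_short),
                 window_long = as.integer(window_long),
                 threshold_short = threshold_short,
                 threshold_long = threshold_long,
                 peak_height = peak_height),
            class = "event_detection_params")
}

# Rolling window means/variances for windows of w samples starting at
# s = 1 .. n-w+1.
rolling_stats <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  s <- 1:(n - w + 1)
  m <- (cs[s + w] - cs[s]) / w
  v <- pmax((cs2[s + w] - cs2[s]) / w - m^2, 0)
  list(mean = m, var = v)
}

# Two straddling-window t-statistics for a boundary before sample i
# (1-based).  The short statistic is a plain Welch t on `ws`-sample
# windows.  The long statistic compares `wl`-sample window means but pools
# the noise variance from the short (boundary-adjacent) windows: with short
# event dwells a long window often spans a neighboring level step, and a
# variance taken over the long window would then be dominated by that step
# rather than by noise, masking real boundaries.  Returns length-n vectors,
# zero where undefined.
boundary_tstats <- function(x, ws, wl) {
  n <- length(x)
  tshort <- numeric(n)
  tlong <- numeric(n)
  if (n < 2 * wl) return(list(short = tshort, long = tlong))
  rs <- rolling_stats(x, ws)
  rl <- rolling_stats(x, wl)
  i <- (wl + 1):(n - wl + 1)
  vS_L <- rs$var[i - ws]
  vS_R <- rs$var[i]
  tshort[i] <- abs(rs$mean[i - ws] - rs$mean[i]) /
    sqrt(vS_L / ws + vS_R / ws + 1e-12)
  tlong[i] <- abs(rl$mean[i - wl] - rl$mean[i]) /
    sqrt(vS_L / wl + vS_R / wl + 1e-12)
  list(short = tshort, long = tlong)
}

#' Segment a raw read into events
#'
#' Splits the current trace into spans of approximately constant level
#' (events), each nominally one k-mer dwelling in the pore.  Events cover
#' the read without gaps or overlap; each is summarized by its start sample,
#' length and mean level in instrument units.
#'
#' @param read A [raw_read()] (or bare numeric sample vector).
#' @param params [event_detection_params()].
#' @return A data.frame with columns `start` (0-based sample index),
#'   `length` and `mean`.
#' @export
detect_events <- function(read, params = event_detection_params()) {
  x <- if (inherits(read, "raw_read")) read$samples else as.numeric(read)
  n <- length(x)
  if (n <= 2 * params$window_long) {
    sqm_stop("read too short for event detection", "sqm_too_short_error")
  }
  st <- boundary_tstats(x, params$window_short, params$window_long)
  ts <- st$short
  tl <- st$long
  ws <- params$window_short
  # local maxima of the short statistic (strict on the left so plateaus
  # yield a single boundary)
  idx <- (params$window_long + 1):(n - params$window_long + 1)
  cand <- idx[ts[idx] > params$threshold_short &
              tl[idx] > params$threshold_long]
  is_peak <- vapply(cand, function(i) {
    lo <- max(1, i - ws); hi <- min(n, i + ws)
    ts[i] > max(ts[lo:(i - 1)]) && ts[i] >= max(ts[i:hi]) &&
      (ts[i] - min(ts[lo:hi])) >= params$peak_height
  }, NA)
  bounds <- cand[is_peak]
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  cs <- c(0, cumsum(x))
  means <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  data.frame(start = starts - 1L,
             length = ends - starts + 1L,
             mean = means)
}

#' Trim the adapter prefix and select the query events
#'
#' Drops the first `prefix_trim` events (nominally the library adapter) and
#' returns the next `query_size` events, the fixed-length window sent to the
#' sDTW engine.
#'
#' @param events Event data.frame from [detect_events()].
#' @param prefix_trim Events to discard from the front (default 50).
#' @param query_size Events to keep after the trim (default 250).
#' @return The selected rows of `events`, in order.
#' @export
trim_and_select <- function(events, prefix_trim = 50L, query_size = 250L) {
  if (nrow(events) < prefix_trim + query_size) {
    sqm_stop(sprintf("insufficient events: %d < %d + %d",
                     nrow(events), prefix_trim, query_size),
             "sqm_insufficient_events_error")
  }
  events[(prefix_trim + 1):(prefix_trim + query_size), , drop = FALSE]
}

#' Prepare a fixed-length event query from a raw read
#'
#' Composes event detection, adapter trimming/selection, z-normalization of
#' the selected event means, and fixed-point quantization with the same
#' scaling factor used for the reference.
#'
#' @param read A [raw_read()].
#' @param params [event_detection_params()].
#' @param prefix_trim,query_size See [trim_and_select()].
#' @param fp [fp_config()]; must match the reference index.
#' @return An object of class `event_query` with fields `read_id`,
#'   `means_float`, `means_quant`, `fp`, `n_prefix_trimmed`,
#'   `n_events_total` and `last_sample` (0-based index of the final sample
#'   covered by the last selected event — useful for truth-based
#'   evaluation).
#' @export
prepare_query <- function(read, params = event_detection_params(),
                          prefix_trim = 50L, query_size = 250L,
                          fp = fp_config()) {
  stopifnot(inherits(read, "raw_read"))
  events <- detect_events(read, params)
  sel <- trim_and_select(events, prefix_trim, query_size)
  z <- znormalize(sel$mean)
  q <- quantize(as.numeric(z), fp)
  last <- sel$start[nrow(sel)] + sel$length[nrow(sel)] - 1L
  structure(list(read_id = read$read_id,
                 means_float = as.numeric(z),
                 means_quant = as.integer(q),
                 fp = fp,
                 n_prefix_trimmed = as.integer(prefix_trim),
                 n_events_total = nrow(events),
                 last_sample = as.integer(last)),
            class = "event_query")
}

#' @export
print.event_query <- function(x, ...) {
  cat(sprintf("<event_query> '%s': %d events (of %d detected, %d trimmed)\n",
              x$read_id, length(x$means_float), x$n_events_total,
              x$n_prefix_trimmed))
  invisible(x)
}
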