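#' Expected alignment end for a simulated read
#'
#' Derives, from the simulation truth, where a query assembled with the
#' given trim/size settings *should* end on the reference: the k-mer window
#' that was in the pore when the final sample of the last selected event
#' was recorded.  Defined this way the expectation is robust to event
#' splits and merges in the detector — it asks about samples, not event
#' counts.
#'
#' @param truth One per-read truth record from [simulate_reads()].
#' @param last_sample 0-based index of the final sample covered by the last
#'   selected query event (field `last_sample` of [prepare_query()]).
#' @return List with `strand` and `end_event` (0-based expected end index
#'   on that strand's signal array), or `end_event = NA` when the query
#'   ends inside the adapter segment.
#' @export
expected_end_event <- function(truth, last_sample) {
  ends <- cumsum(truth$event_dwells)          # 1-based last sample per event
  j <- findInterval(last_sample + 1, c(0, ends), left.open = TRUE)
  j <- min(j, length(ends))
  g <- j - truth$n_adapter_events             # genomic window count covered
  if (g < 1) {
    return(list(strand = truth$strand, end_event = NA_integer_))
  }
  list(strand = truth$strand,
       end_event = truth$start_window + g - 2L)   # 0-based signal index
}

#' Truth-based end-position recovery over a simulated batch
#'
#' Maps every simulated read and scores it against the simulation truth: a
#' read counts as recovered when it maps to the true strand with an end
#' position within `tol` signal positions (approximately bases) of the
#' expected end.  Reads whose query cannot be assembled, or whose query
#' ends inside the adapter, count as failures — the denominator is all
#' simulated reads.
#'
#' @param sim A [simulate_reads()] result.
#' @param idx A [build_reference_index()] built from the same reference and
#'   model.
#' @param params [event_detection_params()].
#' @param engine Engine name for [map_query()].
#' @param trims,query_size See [map_read()].
#' @param tol Tolerance in signal positions (default 5).
#' @return List with `fraction` (recovered / total) and `details`, a
#'   per-read data.frame.
#' @export
evaluate_recovery <- function(sim, idx, params = event_detection_params(),
                              engine = "wavefront",
                              trims = seq(50L, 300L, by = 50L),
                              query_size = 250L, tol = 5L) {
  n <- length(sim$reads)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    read <- sim$reads[[i]]
    truth <- sim$truth[[i]]
    row <- data.frame(read_id = read$read_id, matched = FALSE,
                      strand = NA_character_, end_event = NA_integer_,
                      expected_end = NA_integer_, prefix_trim = NA_integer_,
                      stringsAsFactors = FALSE)
    ok <- tryCatch({
      m <- map_read(read, idx, params, engine, trims, query_size)
      exp <- expected_end_event(truth, m$last_sample)
      row$strand <- m$strand
      row$end_event <- m$end_event
      row$expected_end <- exp$end_event
      row$prefix_trim <- m$prefix_trim
      row$matched <- !is.na(exp$end_event) &&
        identical(m$strand, exp$strand) &&
        abs(m$end_event - exp$end_event) <= tol
      TRUE
    }, squigglemap_error = function(e) FALSE)
    rows[[i]] <- row
  }
  details <- do.call(rbind, rows)
  list(fraction = mean(details$matched), details = details)
}

# Assemble one float query per read, choosing the adapter trim by the
# lowest per-event float score (so the trim choice is independent of any
# scaling factor).  Returns NULL where no usable query exists.
prepare_float_queries <- function(reads, params, trims, query_size,
                                  sig_f, sig_r) {
  lapply(reads, function(r) {
    tryCatch({
      ev <- detect_events(r, params)
      feasible <- trims[trims + query_size <= nrow(ev)]
      if (!length(feasible)) return(NULL)
      best <- NULL
      for (t in feasible) {
        z <- tryCatch(as.numeric(znormalize(
          trim_and_select(ev, t, query_size)$mean)),
          squigglemap_error = function(e) NULL)
        if (is.null(z)) next
        hit <- run_two_strands(z, sig_f, sig_r,
                               function(q, s) sdtw(q, s, engine = "linear"))
        if (is.null(best) || hit$score < best$hit$score) {
          best <- list(z = z, hit = hit)
        }
      }
      best
    }, squigglemap_error = function(e) NULL)
  })
}

run_two_strands <- function(x, sig_f, sig_r, engine_fun) {
  fw <- engine_fun(x, sig_f)
  rv <- engine_fun(x, sig_r)
  if (fw$score <= rv$score) list(strand = "+", end = fw$end, score = fw$score)
  else list(strand = "-", end = rv$end, score = rv$score)
}

#' Wavefront-vs-float agreement across scaling factors
#'
#' For each scaling factor, quantizes reference and queries, maps every
#' read with the fixed-point wavefront engine, and reports the fraction of
#' reads whose (strand, end position) agrees with the 64-bit float
#' linear-space engine within `tol` signal positions.  This is the
#' desk-scale analogue of sweeping the hardware scaling factor: small
#' scales lose resolution, large scales overflow the 16-bit accumulators
#' (under wraparound) and agreement collapses.
#'
#' @param sim A [simulate_reads()] result.
#' @param ref_seq The reference the reads were simulated from.
#' @param model The [pore_model()] used.
#' @param scales Integer vector of scaling factors to sweep.
#' @param bits Word width (default 16).
#' @param overflow Overflow policy (default `"wraparound"`).
#' @param params,trims,query_size Query assembly settings; the trim is
#'   chosen once per read with the float engine and then held fixed across
#'   all scales, so the sweep isolates the quantization effect.
#' @param tol Agreement tolerance in signal positions (default 0: the end
#'   positions must agree exactly).
#' @return Data.frame with columns `scale`, `match_fraction`, `n_reads`.
#' @export
match_fraction_by_scale <- function(sim, ref_seq, model,
                                    scales = c(2L, 4L, 8L, 16L, 32L),
                                    bits = 16L, overflow = "wraparound",
                                    params = event_detection_params(),
                                    trims = seq(50L, 300L, by = 50L),
                                    query_size = 250L, tol = 0L) {
  fp0 <- fp_config(bits = bits, scale = 1L, overflow = overflow)
  idx0 <- build_reference_index(ref_seq, model, fp0, name = "sweep")
  sig_f <- idx0$strands[["+"]]$float_signal
  sig_r <- idx0$strands[["-"]]$float_signal
  fqs <- prepare_float_queries(sim$reads, params, trims, query_size,
                               sig_f, sig_r)
  fqs <- Filter(Negate(is.null), fqs)
  out <- lapply(scales, function(sc) {
    fp <- fp_config(bits = bits, scale = as.integer(sc), overflow = overflow)
    yf <- as.integer(quantize(sig_f, fp))
    yr <- as.integer(quantize(sig_r, fp))
    hits <- vapply(fqs, function(fq) {
      x <- as.integer(quantize(fq$z, fp))
      wf <- run_two_strands(x, yf, yr,
                            function(q, s) sdtw(q, s, engine = "wavefront",
                                                fp = fp))
      identical(wf$strand, fq$hit$strand) && abs(wf$end - fq$hit$end) <= tol
    }, NA)
    data.frame(scale = sc, match_fraction = mean(hits),
               n_reads = length(fqs))
  })
  do.call(rbind, out)
}
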