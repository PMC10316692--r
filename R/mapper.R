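#' Mapping quality from best and second-best alignment scores
#'
#' Summarizes confidence that the best alignment location is correct on the
#' conventional 0–60 scale.  The formula is this package's own: with no
#' second candidate the mapping is unambiguous (60); when the runner-up is
#' as good as the best there is no evidence for the location (0); otherwise
#' quality grows with the relative separation,
#' `min(60, floor(60 * (second - best) / second))`.
#'
#' @param best_score Best (lowest) sDTW score; must be >= 0.
#' @param second_score Second-best score outside the exclusion window, or
#'   `NA` if none exists.
#' @return Integer in \[0, 60\].
#' @examples
#' compute_mapq(0, 100)   # 60
#' compute_mapq(50, 50)   # 0
#' compute_mapq(40, 50)   # 12
#' @export
compute_mapq <- function(best_score, second_score = NA_real_) {
  if (!is.finite(best_score) || best_score < 0) {
    sqm_stop("`best_score` must be finite and non-negative",
             "sqm_domain_error")
  }
  if (is.na(second_score)) return(60L)
  if (second_score < 0) {
    sqm_stop("`second_score` must be non-negative", "sqm_domain_error")
  }
  if (second_score <= best_score) return(0L)
  if (best_score == 0) return(60L)
  as.integer(min(60, floor(60 * (second_score - best_score) / second_score)))
}

#' Selection policy for accept/reject decisions
#'
#' @param target_regions Data.frame with columns `ref`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_bed_regions()], or `NULL` to
#'   accept any location.
#' @param mapq_min Minimum mapping quality to accept (default 20).
#' @param score_max Optional maximum accepted per-event mean distance,
#'   `score / (scale * M)`, in normalized float units; `NULL` disables the
#'   check.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(target_regions = NULL, mapq_min = 20L,
                             score_max = NULL) {
  if (mapq_min < 0 || mapq_min > 60) {
    sqm_stop("`mapq_min` must lie in [0, 60]", "sqm_config_error")
  }
  if (!is.null(target_regions)) {
    stopifnot(all(c("ref", "start", "end") %in% names(target_regions)))
  }
  structure(list(target_regions = target_regions,
                 mapq_min = as.integer(mapq_min),
                 score_max = score_max),
            class = "selection_policy")
}

#' Read target regions from a BED file
#'
#' Standard 0-based half-open BED intervals, converted to the 1-based
#' inclusive convention used internally.
#'
#' @param path BED file path.
#' @return Data.frame with columns `ref`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) {
    sqm_stop(paste0("BED file not found: ", path), "sqm_io_error")
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(ref = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),   # already 1-based inclusive
             end = GenomicRanges::end(gr))
}

# event coordinate -> 1-based base interval on the forward reference.
# Forward strand: signal index e (0-based) is the k-mer window over bases
# [e+1, e+k]; the alignment end is the window's last base, e + k, and the
# nominal span is one base per query event.  Reverse strand: signal index e
# on the reverse-complement maps to forward bases [L-e-k+1, L-e]; the span
# extends toward larger forward coordinates.
event_to_base <- function(end_event, strand, M, k, L) {
  if (strand == "+") {
    end_base <- end_event + k
    start_base <- max(1L, end_base - M + 1L)
  } else {
    start_base <- max(1L, L - end_event - k + 1L)
    end_base <- min(L, start_base + M - 1L)
  }
  list(start_base = as.integer(start_base), end_base = as.integer(end_base))
}

#' Map one event query against a two-strand reference index
#'
#' Runs the chosen sDTW engine on both strands, keeps the strand with the
#' lower best score (forward wins exact ties), converts the winning end
#' position to forward-reference base coordinates, and derives MAPQ from
#' the best score against the strongest competing candidate (the other
#' strand's best, or the same strand's second-best outside the exclusion
#' window).
#'
#' @param q An [prepare_query()] result.
#' @param idx A [build_reference_index()].
#' @param engine `"wavefront"` (fixed-point, default), `"linear"` or
#'   `"oracle"` (both float).
#' @return An object of class `mapping_result` (a list; see [map_batch()]
#'   for the tabular form).
#' @export
map_query <- function(q, idx, engine = c("wavefront", "linear", "oracle")) {
  engine <- match.arg(engine)
  stopifnot(inherits(q, "event_query"), inherits(idx, "reference_index"))
  if (!fp_identical(q$fp, idx$fp)) {
    sqm_stop("query and index fixed-point configurations differ",
             "sqm_config_error")
  }
  M <- length(q$means_float)
  run <- function(strand) {
    if (engine == "wavefront") {
      sdtw(q$means_quant, idx$strands[[strand]]$quant_signal,
           engine = "wavefront", fp = idx$fp)
    } else {
      sdtw(q$means_float, idx$strands[[strand]]$float_signal,
           engine = engine)
    }
  }
  fw <- run("+")
  rv <- run("-")
  strand <- if (fw$score <= rv$score) "+" else "-"
  best <- if (strand == "+") fw else rv
  other <- if (strand == "+") rv else fw
  competitors <- c(other$score,
                   if (!is.na(best$second_score)) best$second_score)
  second <- if (length(competitors)) min(competitors) else NA_real_
  # fixed-point scores can wrap negative; MAPQ needs non-negative inputs
  mapq <- if (best$score < 0) 0L else {
    compute_mapq(best$score, if (!is.na(second) && second >= 0) second
                             else NA_real_)
  }
  coords <- event_to_base(best$end, strand, M, idx$k, idx$base_length)
  structure(list(read_id = q$read_id,
                 mapped = TRUE,
                 strand = strand,
                 ref_name = idx$name,
                 score = best$score,
                 score_float = best$score /
                   if (engine == "wavefront") idx$fp$scale else 1,
                 end_event = best$end,
                 start_base = coords$start_base,
                 end_base = coords$end_base,
                 mapq = mapq,
                 decision = NA_character_,
                 engine = engine,
                 second_score = second,
                 second_end = best$second_end,
                 n_overflow = if (is.null(best$n_overflow)) 0
                              else best$n_overflow,
                 M = M),
            class = "mapping_result")
}

#' Apply a selection policy to a mapping result
#'
#' Accepts a read when it mapped with quality at least `mapq_min`, its base
#' interval overlaps a target region by at least one base (any location if
#' no regions are set), and, if configured, its per-event mean distance is
#' at most `score_max`.  Unmapped reads keep decision `"unmapped"`.
#'
#' @param m A [map_query()] result (or an unmapped `mapping_result`).
#' @param policy A [selection_policy()].
#' @return `m` with `decision` set to `"accept"`, `"reject"` or
#'   `"unmapped"`.
#' @export
apply_selection <- function(m, policy = selection_policy()) {
  stopifnot(inherits(m, "mapping_result"))
  if (!isTRUE(m$mapped)) {
    m$decision <- "unmapped"
    return(m)
  }
  ok <- m$mapq >= policy$mapq_min
  if (ok && !is.null(policy$target_regions)) {
    tr <- policy$target_regions
    ok <- any(tr$ref == m$ref_name &
              tr$start <= m$end_base &
              tr$end >= m$start_base)
  }
  if (ok && !is.null(policy$score_max)) {
    # per-event mean distance in normalized float units, comparable across
    # query sizes and scaling factors
    ok <- m$score_float / m$M <= policy$score_max
  }
  m$decision <- if (ok) "accept" else "reject"
  m
}

#' Two-strand search-space size of an index
#'
#' The dataset-table convention for the size of the signal search space:
#' both strands counted in bases, i.e. `2 * base_length`.  (The per-strand
#' signal arrays actually hold `base_length - k + 1` values each; those
#' lengths are available from the index itself.)
#'
#' @param idx A [build_reference_index()].
#' @return Integer, `2 * base_length`.
#' @examples
#' \dontrun{search_space_size(idx_29903)  # 59806}
#' @export
search_space_size <- function(idx) {
  stopifnot(inherits(idx, "reference_index"))
  2L * as.integer(idx$base_length)
}

#' Map one raw read, selecting the adapter trim adaptively
#'
#' Adapters occupy anywhere from 50 to 300 leading events, so a single
#' fixed trim can leave most of a query filled with adapter signal and
#' make the end position unrecoverable.  `map_read` therefore assembles a
#' candidate query for every feasible trim in `trims`, maps each, and
#' keeps the candidate with the lowest per-event mean distance
#' (`score / (scale * M)`); ties go to the smallest trim.  Passing a
#' single value in `trims` recovers the fixed-trim behaviour.
#'
#' @param read A [raw_read()].
#' @param idx A [build_reference_index()].
#' @param params [event_detection_params()].
#' @param engine Engine name; see [map_query()].
#' @param trims Candidate adapter trims in events (default
#'   `seq(50, 300, by = 50)`, spanning the plausible adapter range).
#' @param query_size Query length in events (default 250).
#' @return A `mapping_result` with additional fields `prefix_trim` (the
#'   selected trim) and `last_sample` (from the selected query).
#' @export
map_read <- function(read, idx, params = event_detection_params(),
                     engine = c("wavefront", "linear", "oracle"),
                     trims = seq(50L, 300L, by = 50L), query_size = 250L) {
  engine <- match.arg(engine)
  events <- detect_events(read, params)
  feasible <- trims[trims + query_size <= nrow(events)]
  if (length(feasible) == 0) {
    sqm_stop(sprintf("insufficient events: %d < %d + %d", nrow(events),
                     min(trims), query_size),
             "sqm_insufficient_events_error")
  }
  best <- NULL
  for (t in feasible) {
    m <- tryCatch({
      sel <- trim_and_select(events, t, query_size)
      z <- znormalize(sel$mean)
      q <- structure(list(read_id = read$read_id,
                          means_float = as.numeric(z),
                          means_quant = as.integer(quantize(as.numeric(z),
                                                            idx$fp)),
                          fp = idx$fp, n_prefix_trimmed = as.integer(t),
                          n_events_total = nrow(events),
                          last_sample = as.integer(
                            sel$start[nrow(sel)] + sel$length[nrow(sel)] - 1L)),
                     class = "event_query")
      m <- map_query(q, idx, engine)
      m$prefix_trim <- as.integer(t)
      m$last_sample <- q$last_sample
      m
    }, sqm_degenerate_error = function(e) NULL)
    if (is.null(m)) next
    if (is.null(best) || m$score_float / m$M < best$score_float / best$M) {
      best <- m
    }
  }
  if (is.null(best)) {
    sqm_stop("no candidate trim produced a usable query",
             "sqm_degenerate_error")
  }
  best
}

unmapped_result <- function(read_id, reason, engine) {
  structure(list(read_id = read_id, mapped = FALSE, strand = NA_character_,
                 ref_name = NA_character_, score = NA_real_,
                 score_float = NA_real_, end_event = NA_integer_,
                 start_base = NA_integer_, end_base = NA_integer_,
                 mapq = NA_integer_, decision = "unmapped", engine = engine,
                 second_score = NA_real_, second_end = NA_integer_,
                 n_overflow = NA_real_, M = NA_integer_, reason = reason),
            class = "mapping_result")
}

result_row <- function(m) {
  data.frame(read_id = m$read_id, mapped = m$mapped, strand = m$strand,
             ref_name = m$ref_name, score = m$score,
             score_float = m$score_float, end_event = m$end_event,
             start_base = m$start_base, end_base = m$end_base,
             mapq = m$mapq, decision = m$decision, engine = m$engine,
             second_score = m$second_score, n_overflow = m$n_overflow,
             reason = if (is.null(m$reason)) NA_character_ else m$reason,
             stringsAsFactors = FALSE)
}

#' Map a batch of raw reads end to end
#'
#' For each read: event detection, adapter trim, query assembly, sDTW
#' mapping on both strands, MAPQ, and the accept/reject decision.  Reads
#' failing query preparation (too short, degenerate signal) appear as
#' unmapped rows with a reason; per-read failures never abort the batch.
#' The output is a pure function of the inputs and is ordered as the input.
#'
#' @param reads List of [raw_read()] (e.g. from [read_raw_reads()]).
#' @param idx A [build_reference_index()].
#' @param params [event_detection_params()].
#' @param policy [selection_policy()].
#' @param engine Engine name; see [map_query()].
#' @param trims,query_size See [map_read()].
#' @return List with `results` (one data.frame row per read, input order)
#'   and `summary` (named counts: accept, reject, unmapped total and
#'   by reason).
#' @export
map_batch <- function(reads, idx, params = event_detection_params(),
                      policy = selection_policy(),
                      engine = c("wavefront", "linear", "oracle"),
                      trims = seq(50L, 300L, by = 50L), query_size = 250L) {
  engine <- match.arg(engine)
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    m <- tryCatch({
      apply_selection(map_read(r, idx, params, engine, trims, query_size),
                      policy)
    },
    sqm_too_short_error = function(e) unmapped_result(r$read_id, "too_short", engine),
    sqm_insufficient_events_error = function(e)
      unmapped_result(r$read_id, "insufficient_events", engine),
    sqm_degenerate_error = function(e)
      unmapped_result(r$read_id, "degenerate_signal", engine))
    rows[[i]] <- result_row(m)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    result_row(unmapped_result("x", "none", engine))[0, ]
  reasons <- table(results$reason[!results$mapped])
  summary <- list(n = nrow(results),
                  accept = sum(results$decision == "accept", na.rm = TRUE),
                  reject = sum(results$decision == "reject", na.rm = TRUE),
                  unmapped = sum(!results$mapped),
                  unmapped_by_reason = as.list(reasons))
  list(results = results, summary = summary)
}

#' Write mapping results as a PAF-like TSV
#'
#' One row per read: `read_id, query_length_events, qstart, qend, strand,
#' ref_name, ref_length_bases, start_base, end_base, score_fixed, mapq`,
#' plus tags `dc:` (decision), `se:` (second-best score) and `ov:`
#' (overflow count).
#'
#' @param batch A [map_batch()] result.
#' @param idx The index the batch was mapped against.
#' @param path Output path.
#' @param query_size Query length in events (default 250).
#' @return `path`, invisibly.
#' @export
write_paf <- function(batch, idx, path, query_size = 250L) {
  r <- batch$results
  fmt <- function(v) ifelse(is.na(v), "*", as.character(v))
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%s\t%s\t%s\t%s\tdc:Z:%s\tse:f:%s\tov:i:%s",
                   r$read_id, query_size, 0L, query_size,
                   fmt(r$strand), fmt(r$ref_name), idx$base_length,
                   fmt(r$start_base), fmt(r$end_base), fmt(r$score),
                   fmt(r$mapq), fmt(r$decision), fmt(r$second_score),
                   fmt(r$n_overflow))
  writeLines(lines, path)
  invisible(path)
}
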