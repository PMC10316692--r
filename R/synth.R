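#' Simulation parameters
#'
#' Defaults emulate the preprocessing regime the mapper is built for: a
#' read begins with an adapter segment of 50–300 events, followed by at
#' least 400 genomic events — enough raw data that the default 50-event
#' trim plus 250-event query can always be assembled.  Events dwell a
#' geometric number of samples (minimum 4, mean 10) and carry Gaussian
#' level noise.
#'
#' @param noise_sigma Level noise standard deviation in model units
#'   (default 0.5).
#' @param dwell_mean Mean samples per event (default 10).
#' @param dwell_dist `"geometric"` (shifted, minimum `dwell_min`) or
#'   `"fixed"` (every event dwells `dwell_mean` samples).
#' @param dwell_min Minimum dwell in samples (default 4; keeps events
#'   resolvable by the default detection windows).
#' @param adapter_range Integer range of adapter event counts, drawn
#'   uniformly (default `c(50, 300)`).
#' @param read_events Number of genomic events per read (default 400).
#' @param revcomp_prob Probability a read comes from the reverse strand
#'   (default 0.5).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(noise_sigma = 0.5, dwell_mean = 10,
                       dwell_dist = c("geometric", "fixed"), dwell_min = 4L,
                       adapter_range = c(50L, 300L), read_events = 400L,
                       revcomp_prob = 0.5) {
  dwell_dist <- match.arg(dwell_dist)
  stopifnot(noise_sigma >= 0, dwell_mean >= dwell_min, dwell_min >= 1,
            revcomp_prob >= 0, revcomp_prob <= 1,
            length(adapter_range) == 2, adapter_range[1] <= adapter_range[2])
  structure(list(noise_sigma = noise_sigma, dwell_mean = dwell_mean,
                 dwell_dist = dwell_dist, dwell_min = as.integer(dwell_min),
                 adapter_range = as.integer(adapter_range),
                 read_events = as.integer(read_events),
                 revcomp_prob = revcomp_prob),
            class = "sim_params")
}

#' Generate a complete synthetic pore model
#'
#' Levels are an evenly spaced grid over 60–140 model units with a small
#' uniform jitter, assigned to the 4^k k-mers in random order.  The grid
#' guarantees that distinct k-mers keep a minimum level gap (half the grid
#' spacing), so level steps between most consecutive windows of a random
#' sequence are detectable by the event segmenter.
#'
#' @param k K-mer length, 1–8.
#' @param seed RNG seed; generation is a pure function of `(k, seed)`.
#' @return A complete [pore_model()].
#' @export
generate_pore_model <- function(k, seed = 1L) {
  stopifnot(is_count(k), k >= 1, k <= 8)
  n <- 4L^k
  with_seed(seed, {
    grid <- if (n == 1) 100 else seq(60, 140, length.out = n)
    spacing <- if (n == 1) 1 else grid[2] - grid[1]
    levels <- grid + runif(n, -spacing / 4, spacing / 4)
    bases <- c("A", "C", "G", "T")
    kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                             stringsAsFactors = FALSE)))
    pore_model(stats::setNames(levels, sample(kmers)))
  })
}

#' Generate a random reference sequence
#'
#' @param length_bases Sequence length (>= 1).
#' @param seed RNG seed.
#' @return A single uppercase ACGT string; deterministic per seed.
#' @export
generate_reference <- function(length_bases, seed = 1L) {
  if (!is_count(length_bases)) {
    sqm_stop("`length_bases` must be a positive integer", "sqm_size_error")
  }
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length_bases,
                               replace = TRUE), collapse = ""))
}

draw_dwells <- function(n, params) {
  if (params$dwell_dist == "fixed") {
    rep(as.integer(round(params$dwell_mean)), n)
  } else {
    p <- 1 / (params$dwell_mean - params$dwell_min + 1)
    params$dwell_min + rgeom(n, p)
  }
}

# Adapter levels sit outside the central band of the 60-140 model range
# and alternate between a low and a high side, so consecutive adapter
# events always present a detectable step.
draw_adapter_levels <- function(n) {
  side <- (seq_len(n) + sample.int(2, 1)) %% 2 == 0
  ifelse(side, runif(n, 128, 150), runif(n, 50, 72))
}

#' Simulate one raw read with known truth
#'
#' Picks a strand and a uniform start position, takes the pore-model levels
#' along the (possibly reverse-complemented) reference as true event
#' levels, prepends an adapter segment, expands each event to its dwell in
#' samples, and adds Gaussian level noise.
#'
#' @param ref_seq Reference base string.
#' @param model A [pore_model()].
#' @param params A [sim_params()].
#' @param seed RNG seed for this read.
#' @param read_id Identifier for the emitted read.
#' @return List with `read` (a [raw_read()]) and `truth`, a list holding
#'   `read_id`, `strand`, `start_base`/`end_base` (1-based inclusive
#'   forward coordinates of the sequenced span), `start_window`
#'   (strand-local first k-mer window, 1-based), `n_adapter_events`,
#'   `event_levels` and `event_dwells` (adapter + genomic, in emission
#'   order).
#' @export
simulate_read <- function(ref_seq, model, params = sim_params(), seed = 1L,
                          read_id = "read") {
  k <- model$k
  L <- nchar(ref_seq)
  R <- params$read_events
  n_windows <- L - k + 1L
  if (n_windows < R) {
    sqm_stop("reference too short for the requested read length",
             "sqm_size_error")
  }
  with_seed(seed, {
    strand <- if (runif(1) < params$revcomp_prob) "-" else "+"
    seq_strand <- if (strand == "-") reverse_complement(ref_seq) else
      toupper(ref_seq)
    s_w <- sample.int(n_windows - R + 1L, 1)
    sub <- substr(seq_strand, s_w, s_w + R + k - 2L)
    genomic_levels <- sequence_to_signal(sub, model)
    n_adapter <- params$adapter_range[1] +
      sample.int(params$adapter_range[2] - params$adapter_range[1] + 1L,
                 1L) - 1L
    levels <- c(draw_adapter_levels(n_adapter), genomic_levels)
    dwells <- draw_dwells(length(levels), params)
    samples <- rep(levels, dwells)
    if (params$noise_sigma > 0) {
      samples <- samples + rnorm(length(samples), 0, params$noise_sigma)
    }
    if (strand == "+") {
      start_base <- s_w
      end_base <- s_w + R + k - 2L
    } else {
      start_base <- L - (s_w + R - 1L) - k + 2L
      end_base <- L - s_w + 1L
    }
    list(read = raw_read(read_id, samples),
         truth = list(read_id = read_id, strand = strand,
                      start_base = as.integer(start_base),
                      end_base = as.integer(end_base),
                      start_window = as.integer(s_w),
                      n_adapter_events = as.integer(n_adapter),
                      event_levels = levels, event_dwells = dwells))
  })
}

#' Simulate a seeded batch of reads
#'
#' One dataset seed deterministically derives a child seed per read, so a
#' dataset is reproducible read by read regardless of batch composition.
#'
#' @inheritParams simulate_read
#' @param n Number of reads.
#' @param seed Dataset seed.
#' @return List with `reads` (list of [raw_read()]) and `truth` (list of
#'   per-read truth records; `truth_table()` flattens the scalar fields).
#' @export
simulate_reads <- function(ref_seq, model, n, params = sim_params(),
                           seed = 1L) {
  out <- lapply(seq_len(n), function(i) {
    simulate_read(ref_seq, model, params, seed = child_seed(seed, i),
                  read_id = sprintf("sim_%04d", i))
  })
  list(reads = lapply(out, `[[`, "read"),
       truth = lapply(out, `[[`, "truth"))
}

#' Flatten simulation truth records into a table
#'
#' @param truth The `truth` element of [simulate_reads()].
#' @return Data.frame of the scalar truth fields, one row per read.
#' @export
truth_table <- function(truth) {
  do.call(rbind, lapply(truth, function(t) {
    data.frame(read_id = t$read_id, strand = t$strand,
               start_base = t$start_base, end_base = t$end_base,
               start_window = t$start_window,
               n_adapter_events = t$n_adapter_events,
               n_events = length(t$event_levels),
               stringsAsFactors = FALSE)
  }))
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits `ref.fa`, `model.tsv`, `reads.tsv`, `reads.slow5` and `truth.tsv`
#' into a directory.  Re-running with the same seed and spec reproduces
#' identical files.
#'
#' @param outdir Output directory (created if missing).
#' @param ref_seq Reference base string.
#' @param model A [pore_model()].
#' @param n_reads Number of reads to simulate.
#' @param params A [sim_params()].
#' @param seed Dataset seed.
#' @param ref_name FASTA record name (default `"synthetic_ref"`).
#' @return Invisibly, the list returned by [simulate_reads()].
#' @export
write_fixtures <- function(outdir, ref_seq, model, n_reads,
                           params = sim_params(), seed = 1L,
                           ref_name = "synthetic_ref") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reads(ref_seq, model, n_reads, params, seed)
  writeLines(c(paste0(">", ref_name), ref_seq), file.path(outdir, "ref.fa"))
  write_pore_model(model, file.path(outdir, "model.tsv"))
  write_reads_tsv(sim$reads, file.path(outdir, "reads.tsv"))
  write_slow5(sim$reads, file.path(outdir, "reads.slow5"))
  write.table(truth_table(sim$truth), file.path(outdir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}
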