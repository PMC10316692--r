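test_that("compute_mapq follows the best/second separation formula", {
  expect_identical(compute_mapq(0, 100), 60L)
  expect_identical(compute_mapq(50, 50), 0L)
  expect_identical(compute_mapq(40, 50), 12L)
  expect_identical(compute_mapq(10, NA_real_), 60L)
  expect_identical(compute_mapq(0, 5), 60L)
  expect_identical(compute_mapq(60, 50), 0L)
  expect_error(compute_mapq(-1, 5), class = "sqm_domain_error")
  expect_error(compute_mapq(1, -5), class = "sqm_domain_error")
  # monotone non-decreasing in (second - best) at fixed second
  second <- 200
  q <- vapply(seq(200, 0, by = -5),
              function(b) compute_mapq(b, second), 1L)
  expect_true(all(diff(q) >= 0))
})

test_that("search_space_size follows the two-strand base-count convention", {
  m <- generate_pore_model(6, seed = 1)
  idx <- build_reference_index(generate_reference(5000, seed = 2), m,
                               fp_config())
  expect_identical(search_space_size(idx), 10000L)
  # boundary: a single-base reference cannot be signal-indexed (one window
  # cannot be z-normalized) but the statistic itself is defined
  idx1 <- structure(list(base_length = 1L), class = "reference_index")
  expect_identical(search_space_size(idx1), 2L)
})

test_that("planted forward-strand queries map exactly with correct coordinates", {
  m <- generate_pore_model(4, seed = 41)
  ref <- generate_reference(2000, seed = 42)
  fp <- fp_config()
  idx <- build_reference_index(ref, m, fp, name = "plant")
  q <- fabricate_quant_query(idx$strands[["+"]]$quant_signal[101:350], fp)
  r <- map_query(q, idx)
  expect_true(r$mapped)
  expect_identical(r$strand, "+")
  expect_identical(r$score, 0)
  expect_identical(r$end_event, 349L)
  expect_identical(r$end_base, 349L + idx$k)
  expect_identical(r$start_base, 349L + idx$k - 250L + 1L)
  expect_identical(r$mapq, 60L)
})

test_that("planted reverse-strand queries return forward coordinates", {
  m <- generate_pore_model(4, seed = 41)
  ref <- generate_reference(2000, seed = 43)
  fp <- fp_config()
  idx <- build_reference_index(ref, m, fp, name = "plant")
  L <- idx$base_length
  e0 <- 500L
  q <- fabricate_quant_query(
    idx$strands[["-"]]$quant_signal[(e0 - 249L + 1L):(e0 + 1L)], fp)
  r <- map_query(q, idx)
  expect_identical(r$strand, "-")
  expect_identical(r$end_event, e0)
  # reverse signal index e covers forward bases [L - e - k + 1, L - e];
  # the reported interval must contain that window
  expect_identical(r$start_base, L - e0 - idx$k + 1L)
  expect_identical(r$end_base, min(L, r$start_base + 250L - 1L))
  # the plant covers reverse windows e0-249 .. e0, i.e. forward bases
  # [L - e0 - k + 1, L - (e0 - 249)]: start must sit at the interval start
  expect_true(r$start_base >= 1 && r$end_base <= L)
})

test_that("a flat far-off query maps with (near) zero mapping quality", {
  m <- generate_pore_model(4, seed = 41)
  ref <- generate_reference(2000, seed = 44)
  fp <- fp_config()
  idx <- build_reference_index(ref, m, fp)
  # short constant query so accumulated costs stay inside the 16-bit range
  # (a 250-event far-off query would genuinely overflow and wrap negative)
  q <- fabricate_quant_query(rep(200L, 50L), fp)
  r <- map_query(q, idx)
  expect_true(r$mapped)
  # consistency with a brute-force best/second over the per-strand streams
  want <- lapply(c("+", "-"), function(st) {
    sdtw(q$means_quant, idx$strands[[st]]$quant_signal,
         engine = "wavefront", fp = fp)
  })
  st <- if (want[[1]]$score <= want[[2]]$score) 1 else 2
  best <- want[[st]]
  second <- min(want[[3 - st]]$score, best$second_score, na.rm = TRUE)
  expect_identical(r$score, best$score)
  expect_identical(r$mapq, compute_mapq(best$score, second))
  expect_lte(r$mapq, 2L)
})

test_that("fp mismatch between query and index is a configuration error", {
  m <- generate_pore_model(4, seed = 41)
  idx <- build_reference_index(generate_reference(500, seed = 1), m,
                               fp_config(scale = 32L))
  q <- fabricate_quant_query(rep(1L, 10L), fp_config(scale = 64L))
  expect_error(map_query(q, idx), class = "sqm_config_error")
})

test_that("selection policy combines mapq, regions and score thresholds", {
  m <- generate_pore_model(4, seed = 41)
  ref <- generate_reference(2000, seed = 42)
  fp <- fp_config()
  idx <- build_reference_index(ref, m, fp, name = "plant")
  q <- fabricate_quant_query(idx$strands[["+"]]$quant_signal[101:350], fp)
  r <- map_query(q, idx)  # maps at bases [104+1.. ] with mapq 60
  reg <- data.frame(ref = "plant", start = 1L, end = 500L)
  expect_identical(apply_selection(r, selection_policy(reg))$decision,
                   "accept")
  # one-base overlap at the region edge still accepts
  edge <- data.frame(ref = "plant", start = 1L, end = r$start_base)
  expect_identical(apply_selection(r, selection_policy(edge))$decision,
                   "accept")
  miss <- data.frame(ref = "plant", start = 1L, end = r$start_base - 1L)
  expect_identical(apply_selection(r, selection_policy(miss))$decision,
                   "reject")
  # mapq gate
  r2 <- r
  r2$mapq <- 5L
  expect_identical(apply_selection(r2, selection_policy(reg))$decision,
                   "reject")
  # per-event score gate: a zero-score plant passes any positive threshold
  expect_identical(
    apply_selection(r, selection_policy(reg, score_max = 0.1))$decision,
    "accept")
})

test_that("BED regions are converted to 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t99\t200", f)
  reg <- read_bed_regions(f)
  expect_identical(reg$ref, "chrA")
  expect_identical(reg$start, 100L)
  expect_identical(reg$end, 200L)
})

test_that("map_batch is deterministic, ordered and robust to bad reads", {
  m <- generate_pore_model(5, seed = 51)
  ref <- generate_reference(3000, seed = 52)
  fp <- fp_config()
  idx <- build_reference_index(ref, m, fp, name = "batch")
  sim <- simulate_reads(ref, m, 6, sim_params(noise_sigma = 0.3), seed = 53)
  reads <- c(sim$reads, list(raw_read("short", rnorm(12, 100))))
  b <- map_batch(reads, idx)
  expect_identical(nrow(b$results), 7L)
  expect_identical(b$results$read_id,
                   vapply(reads, `[[`, "", "read_id"))
  expect_identical(b$results$reason[7], "too_short")
  expect_false(b$results$mapped[7])
  expect_identical(b$summary$unmapped, 1L)
  expect_identical(b$summary$n, 7L)
  # pure function of inputs
  b2 <- map_batch(reads, idx)
  expect_identical(b2$results, b$results)
  # empty input
  e <- map_batch(list(), idx)
  expect_identical(nrow(e$results), 0L)
  expect_identical(e$summary$accept, 0L)
})

test_that("on-target reads are accepted and foreign reads are not", {
  m <- generate_pore_model(5, seed = 61)
  target <- generate_reference(3000, seed = 62)
  decoy <- generate_reference(3000, seed = 63)
  fp <- fp_config()
  idx <- build_reference_index(target, m, fp, name = "target")
  p <- sim_params(noise_sigma = 0.3)
  on <- simulate_reads(target, m, 15, p, seed = 64)
  off <- simulate_reads(decoy, m, 15, p, seed = 65)
  pol <- selection_policy(data.frame(ref = "target", start = 1L,
                                     end = 3000L))
  b <- map_batch(c(on$reads, off$reads), idx, policy = pol)
  dec <- b$results$decision
  expect_gte(sum(dec[1:15] == "accept"), 14)
  expect_lte(sum(dec[16:30] == "accept"), 1)
})

test_that("PAF-like output has one well-formed row per read", {
  m <- generate_pore_model(5, seed = 51)
  ref <- generate_reference(3000, seed = 52)
  idx <- build_reference_index(ref, m, fp_config(), name = "batch")
  sim <- simulate_reads(ref, m, 3, sim_params(noise_sigma = 0.3), seed = 53)
  b <- map_batch(sim$reads, idx)
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(b, idx, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 14))
  expect_true(all(grepl("^dc:Z:", vapply(fields, `[[`, "", 12))))
})
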