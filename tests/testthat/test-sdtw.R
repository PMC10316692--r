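test_that("worked toy alignments agree with the hand-checked matrices", {
  # exact subsequence: zero cost, free start
  r <- sdtw(c(1, 2), c(0, 1, 2, 3), engine = "oracle")
  expect_equal(r$score, 0)
  expect_equal(r$end, 2L)
  expect_equal(r$start, 1L)
  expect_equal(r$path, matrix(c(0L, 1L, 1L, 2L), 2, 2, byrow = TRUE))
  rl <- sdtw(c(1, 2), c(0, 1, 2, 3), engine = "linear")
  expect_equal(rl$score, 0)
  expect_equal(rl$end, 2L)

  # last row [4, 2, 2, 2]: smallest-index tie-break picks end 1
  for (eng in c("oracle", "linear")) {
    r <- sdtw(c(1, 3), c(0, 2, 4, 2), engine = eng)
    expect_equal(r$score, 2)
    expect_equal(r$end, 1L)
  }
  br <- r_sdtw_full(c(1, 3), c(0, 2, 4, 2))
  expect_equal(br$last_row, c(4, 2, 2, 2))

  # single-sample query: closed form min_j |c - y_j|, first argmin
  y <- c(9, 3, 8, 3)
  r1 <- sdtw(4, y, engine = "oracle")
  expect_equal(r1$score, min(abs(4 - y)))
  expect_equal(r1$end, 1L)
})

test_that("size preconditions are enforced", {
  expect_error(sdtw(c(1, 2, 3), c(1, 2)), class = "sqm_size_error")
  expect_error(sdtw(numeric(), 1), class = "sqm_size_error")
  expect_error(sdtw_fixed_seq(1:3, 1:2), class = "sqm_size_error")
})

test_that("oracle engine matches the direct matrix recurrence", {
  set.seed(101)
  for (t in 1:50) {
    M <- sample(1:8, 1)
    N <- sample(M:14, 1)
    x <- round(rnorm(M), 2)
    y <- round(rnorm(N), 2)
    got <- sdtw(x, y, engine = "oracle")
    want <- r_sdtw_full(x, y)
    expect_identical(got$score, want$score)
    expect_identical(got$end, want$end)
    # path validity: unit steps, monotone, starts in row 0, ends at (M-1, end)
    p <- got$path
    expect_equal(p[1, 1], 0L)
    expect_equal(p[nrow(p), ], c(M - 1L, got$end))
    if (nrow(p) > 1) {
      d <- diff(p)
      expect_true(all(d[, 1] %in% 0:1 & d[, 2] %in% 0:1 & rowSums(d) >= 1))
    }
  }
})

test_that("linear engine equals the oracle exactly on random instances", {
  set.seed(202)
  for (t in 1:200) {
    M <- sample(1:64, 1)
    N <- sample(M:200, 1)
    x <- rnorm(M)
    y <- rnorm(N)
    a <- sdtw(x, y, engine = "linear")
    b <- sdtw(x, y, engine = "oracle")
    expect_identical(a$score, b$score)
    expect_identical(a$end, b$end)
    expect_identical(a$second_score, b$second_score)
    expect_identical(a$second_end, b$second_end)
  }
})

test_that("self-alignment has zero score ending at the last position", {
  set.seed(7)
  x <- rnorm(40)
  r <- sdtw(x, x, engine = "linear")
  expect_equal(r$score, 0)
  expect_equal(r$end, 39L)
})

test_that("score is zero iff the query is an exact subsequence", {
  set.seed(8)
  y <- rnorm(300)
  x <- y[101:140]
  expect_equal(sdtw(x, y)$score, 0)
  x2 <- x
  x2[20] <- x2[20] + 0.7
  expect_gt(sdtw(x2, y)$score, 0)
})

test_that("prepending reference samples shifts the end position exactly", {
  set.seed(9)
  y <- rnorm(400)
  x <- y[201:260] + rnorm(60, 0, 0.05)
  base_end <- sdtw(x, y)$end
  for (p in c(1, 7, 53)) {
    y2 <- c(rep(50, p), y)  # prefix far outside the query range
    expect_equal(sdtw(x, y2)$end, base_end + p)
  }
})

test_that("fixed-point engines are bit-identical to the modular-arithmetic oracle", {
  set.seed(303)
  for (t in 1:60) {
    M <- sample(1:16, 1)
    N <- sample(M:48, 1)
    # values spanning the representable range to exercise overflow paths
    x <- sample(c(-32768:32767), M, replace = TRUE)
    y <- sample(c(-32768:32767), N, replace = TRUE)
    for (wrap in c(TRUE, FALSE)) {
      fp <- fp_config(overflow = if (wrap) "wraparound" else "saturate")
      want <- r_sdtw_fixed(x, y, 16, wrap)
      seqr <- sdtw_fixed_seq(x, y, fp)
      wave <- sdtw(x, y, engine = "wavefront", fp = fp)
      expect_identical(seqr$score, want$score)
      expect_identical(seqr$end, want$end)
      expect_identical(wave$score, want$score)
      expect_identical(wave$end, want$end)
      expect_identical(wave$second_score, seqr$second_score)
      expect_identical(wave$n_overflow, seqr$n_overflow)
    }
  }
})

test_that("wavefront reports M + N - 1 steps and out-of-range inputs fail", {
  fp <- fp_config()
  r <- sdtw(c(1L, 2L, 3L), 1:10, engine = "wavefront", fp = fp)
  expect_identical(r$steps, 12L)
  expect_error(sdtw(c(40000L), 1:10, engine = "wavefront", fp = fp),
               "range")
})

test_that("fixed-point Manhattan distance follows word-width semantics", {
  fp_w <- fp_config(overflow = "wraparound")
  fp_s <- fp_config(overflow = "saturate")
  expect_identical(as.integer(manhattan(3L, 5L, fp_w)), 2L)
  expect_identical(as.integer(manhattan(-120L, -120L, fp_w)), 0L)
  expect_equal(manhattan(c(3, -7), c(5, -7)), c(2, 0))
  # -32768 - 1 wraps to 32767 in 16-bit two's complement
  expect_identical(as.integer(manhattan(-32768L, 1L, fp_w)), 32767L)
  expect_identical(as.integer(manhattan(-32768L, 1L, fp_s)), 32767L)
  # |x - y| where the true difference fits but its negation wraps
  expect_identical(as.integer(manhattan(-32768L, 0L, fp_w)), -32768L)
  expect_identical(as.integer(manhattan(-32768L, 0L, fp_s)), 32767L)
  # random agreement with the masked-arithmetic oracle
  set.seed(11)
  a <- sample(-32768:32767, 200, TRUE)
  b <- sample(-32768:32767, 200, TRUE)
  for (wrap in c(TRUE, FALSE)) {
    fp <- if (wrap) fp_w else fp_s
    d0 <- r_fx_norm(a - b, 16, wrap)
    want <- ifelse(d0 < 0, r_fx_norm(-d0, 16, wrap), d0)
    expect_identical(as.numeric(manhattan(a, b, fp)), want)
  }
})

test_that("best_and_second matches a brute-force double scan", {
  b <- best_and_second(c(4, 2, 2, 2), 0L)
  expect_equal(b$end, 1L)
  expect_equal(b$score, 2)
  expect_equal(b$second_end, 2L)
  expect_equal(b$second_score, 2)

  single <- best_and_second(5, 3L)
  expect_true(is.na(single$second_score))

  expect_error(best_and_second(numeric()), class = "sqm_size_error")

  set.seed(12)
  for (t in 1:50) {
    v <- sample(rnorm(20), sample(1:40, 1), replace = TRUE)
    w <- sample(0:10, 1)
    got <- best_and_second(v, w)
    want <- r_best_second(v, w)
    expect_identical(got$end, want$best$index)
    expect_identical(got$score, want$best$value)
    if (is.null(want$second)) {
      expect_true(is.na(got$second_score))
    } else {
      expect_identical(got$second_end, want$second$index)
      expect_identical(got$second_score, want$second$value)
    }
  }
})

test_that("quantized alignment tracks the float alignment at scale 32", {
  set.seed(404)
  fp <- fp_config()
  for (t in 1:20) {
    y <- pmax(pmin(rnorm(600), 4), -4)
    x <- y[201:280] + rnorm(80, 0, 0.05)
    fl <- sdtw(x, y, engine = "linear")
    wf <- sdtw(as.integer(quantize(x, fp)), as.integer(quantize(y, fp)),
               engine = "wavefront", fp = fp)
    expect_identical(wf$end, fl$end)
    M <- length(x)
    expect_lt(abs(wf$score / 32 - fl$score), 2 * M * (0.5 / 32) * 2)
  }
})

test_that("16-bit wraparound accumulators overflow on long references at scale 256", {
  set.seed(505)
  y <- pmax(pmin(rnorm(60000), 4), -4)
  x <- rnorm(250)
  fp256 <- fp_config(scale = 256L)
  wf <- sdtw(as.integer(quantize(x, fp256)),
             as.integer(quantize(y, fp256)), engine = "wavefront",
             fp = fp256)
  expect_gt(wf$n_overflow, 0)
  fp32 <- fp_config(scale = 32L)
  wf32 <- sdtw(as.integer(quantize(x, fp32)),
               as.integer(quantize(y, fp32)), engine = "wavefront",
               fp = fp32)
  expect_identical(wf32$n_overflow, 0)
  # wrapped cells poison the last-row minimum: the best score goes negative
  expect_lt(wf$score, 0)
  expect_gte(wf32$score, 0)
})
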