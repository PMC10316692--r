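# Independent reference implementations used as oracles.  These are written
# against the recurrence/arithmetic definitions directly (matrix form,
# modular arithmetic on doubles) and share no code with the package engines.

# Full-matrix float sDTW by direct recurrence evaluation.
r_sdtw_full <- function(x, y) {
  M <- length(x)
  N <- length(y)
  G <- matrix(Inf, M + 1, N + 1)
  G[1, ] <- 0
  for (j in 2:(N + 1)) {
    for (i in 2:(M + 1)) {
      G[i, j] <- abs(x[i - 1] - y[j - 1]) +
        min(G[i - 1, j], G[i - 1, j - 1], G[i, j - 1])
    }
  }
  last <- G[M + 1, 2:(N + 1)]
  bi <- which.min(last)
  list(score = last[bi], end = bi - 1L, last_row = last)
}

# Word-width renormalization on doubles via modular arithmetic.
r_fx_norm <- function(v, bits, wrap) {
  lo <- -2^(bits - 1)
  hi <- 2^(bits - 1) - 1
  if (wrap) ((v - lo) %% 2^bits) + lo else pmin(pmax(v, lo), hi)
}

# Sequential fixed-point linear-space sDTW: cost array of M + 1, outer loop
# over the reference, inner over the query; "infinity" boundary is the
# maximum representable value.
r_sdtw_fixed <- function(x, y, bits, wrap) {
  M <- length(x)
  N <- length(y)
  hi <- 2^(bits - 1) - 1
  cost <- rep(hi, M + 1)  # cost[i + 1] holds gamma(i, .)
  cost[1] <- 0
  last <- numeric(N)
  for (j in 1:N) {
    diag <- cost[1]
    for (i in 1:M) {
      up_left <- cost[i + 1]
      d <- r_fx_norm(x[i] - y[j], bits, wrap)
      if (d < 0) d <- r_fx_norm(-d, bits, wrap)
      m <- min(diag, up_left, cost[i])
      diag <- up_left
      cost[i + 1] <- r_fx_norm(d + m, bits, wrap)
    }
    last[j] <- cost[M + 1]
  }
  bi <- which.min(last)
  list(score = last[bi], end = bi - 1L, last_row = last)
}

# Brute-force best/second-best by a double scan.
r_best_second <- function(values, window) {
  bi <- which.min(values)
  best <- list(index = bi - 1L, value = values[bi])
  sv <- Inf
  si <- NA_integer_
  for (j in seq_along(values)) {
    if (abs(j - bi) <= window) next
    if (values[j] < sv) {
      sv <- values[j]
      si <- j - 1L
    }
  }
  list(best = best,
       second = if (is.na(si)) NULL else list(index = si, value = sv))
}

# A fully specified toy pore model over 2-mers.
toy_model <- function() {
  bases <- c("A", "C", "G", "T")
  kmers <- as.vector(outer(bases, bases, paste0))
  pore_model(stats::setNames(seq(60, 140, length.out = 16), sort(kmers)))
}

# Fabricate an event_query directly from float means (bypassing event
# detection) for planted-match tests.
fabricate_query <- function(means_float, fp, read_id = "planted") {
  structure(list(read_id = read_id,
                 means_float = as.numeric(means_float),
                 means_quant = as.integer(quantize(as.numeric(means_float),
                                                   fp)),
                 fp = fp,
                 n_prefix_trimmed = 0L,
                 n_events_total = length(means_float),
                 last_sample = NA_integer_),
            class = "event_query")
}

# Fabricate a query whose quantized means are given exactly.
fabricate_quant_query <- function(quant, fp, read_id = "planted") {
  structure(list(read_id = read_id,
                 means_float = as.numeric(quant) / fp$scale,
                 means_quant = as.integer(quant),
                 fp = fp,
                 n_prefix_trimmed = 0L,
                 n_events_total = length(quant),
                 last_sample = NA_integer_),
            class = "event_query")
}
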