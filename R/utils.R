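# Classed conditions so callers can distinguish failure modes programmatically.
sqm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "squigglemap_error", "error"),
                      call = call))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-item child seed from a dataset seed; keeps everything < 2^31.
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
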