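#' Fixed-point configuration for quantized sDTW
#'
#' Describes the integer arithmetic used by the wavefront engine and the
#' quantizer: the word width of the accumulators, the scaling factor applied
#' to z-normalized signal before rounding, and what happens on accumulator
#' overflow.  The defaults (16-bit words, scale 32) keep one clock-equivalent
#' of precision headroom: too small a scale loses signal resolution, too
#' large a scale overflows the distance accumulation on long references.
#'
#' @param bits Word width in bits of signal values and cost accumulators.
#'   Must be >= 8.  Default 16.
#' @param scale Integer scaling factor applied to z-normalized signal values
#'   before rounding.  Must be >= 1.  Default 32 (i.e. 2^5).
#' @param overflow Overflow policy of the fixed-point arithmetic:
#'   `"wraparound"` (two's-complement wrap, modelling hardware accumulators)
#'   or `"saturate"`.  Default `"wraparound"`.
#' @return An object of class `fp_config`.
#' @examples
#' fp <- fp_config()
#' fp$scale  # 32
#' @export
fp_config <- function(bits = 16L, scale = 32L,
                      overflow = c("wraparound", "saturate")) {
  overflow <- match.arg(overflow)
  if (!is_count(bits, min = 8)) {
    sqm_stop("`bits` must be a single integer >= 8", "sqm_config_error")
  }
  if (!is_count(scale, min = 1)) {
    sqm_stop("`scale` must be a single integer >= 1", "sqm_config_error")
  }
  if (bits > 30) {
    sqm_stop("`bits` above 30 is not supported by the integer engines",
             "sqm_config_error")
  }
  structure(list(bits = as.integer(bits), scale = as.integer(scale),
                 overflow = overflow),
            class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  cat(sprintf("<fp_config> %d-bit, scale %d, overflow policy '%s'\n",
              x$bits, x$scale, x$overflow))
  cat(sprintf("  representable range [%d, %d]\n", fp_min(x), fp_max(x)))
  invisible(x)
}

fp_min <- function(fp) -(2L^(fp$bits - 1L))
fp_max <- function(fp) 2L^(fp$bits - 1L) - 1L

fp_identical <- function(a, b) {
  a$bits == b$bits && a$scale == b$scale && a$overflow == b$overflow
}

#' Quantize a normalized signal into fixed-point integers
#'
#' Multiplies by the scaling factor, rounds to the nearest integer with ties
#' away from zero, and clamps into the representable range of the word
#' width.  Clamping is silent but counted: the number of clamped elements is
#' attached as attribute `"n_clamped"` for diagnostics.
#'
#' @param x Numeric vector, typically z-normalized signal.  Must be finite.
#' @param fp A [fp_config()].
#' @return Integer vector of the same length, with attribute `n_clamped`.
#' @examples
#' quantize(c(-1, 0, 1.5), fp_config(scale = 32L))  # -32 0 48
#' @export
quantize <- function(x, fp = fp_config()) {
  if (!all(is.finite(x))) {
    sqm_stop("`x` must be finite for quantization", "sqm_domain_error")
  }
  v <- x * fp$scale
  q <- sign(v) * floor(abs(v) + 0.5)   # round half away from zero
  lo <- fp_min(fp)
  hi <- fp_max(fp)
  n_clamped <- sum(q < lo | q > hi)
  q <- pmin(pmax(q, lo), hi)
  structure(as.integer(q), n_clamped = as.integer(n_clamped))
}

#' Convert quantized values back to the normalized scale
#'
#' @param q Integer vector produced by [quantize()].
#' @param fp The [fp_config()] used to quantize.
#' @return Numeric vector `q / scale`.
#' @export
dequantize <- function(q, fp = fp_config()) {
  as.numeric(q) / fp$scale
}
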