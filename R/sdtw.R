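#' Subsequence dynamic time warping
#'
#' Locally aligns a short query series `x` anywhere inside a long reference
#' series `y` under Manhattan distance.  The accumulated cost obeys
#' \deqn{\gamma(i,j) = |x_i - y_j| + \min\{\gamma(i-1,j),\,
#'   \gamma(i-1,j-1),\, \gamma(i,j-1)\}}
#' with boundaries \eqn{\gamma(i,0)=\infty} and \eqn{\gamma(0,j)=0} (free
#' start anywhere in the reference).  The alignment ends at the minimum of
#' the last row.
#'
#' Three engines compute the same quantity:
#' \describe{
#'   \item{`oracle`}{full \eqn{M \times N} matrix in double precision, with
#'     backtracking for the warp path and start position.  Memory-hungry;
#'     intended for validation and small problems.}
#'   \item{`linear`}{double precision with a cost array of `M + 1` entries;
#'     returns score and end position only.}
#'   \item{`wavefront`}{bit-accurate model of a fixed-point
#'     processing-element chain evaluating one oblique anti-diagonal per
#'     step; requires integer (quantized) inputs and an [fp_config()].
#'     Reports its step count, `M + N - 1`, and the number of overflow
#'     events under the configured policy.}
#' }
#'
#' Ties are broken deterministically: the last-row argmin takes the
#' smallest reference index; backtracking prefers diagonal, then left
#' (j-1), then up (i-1).
#'
#' @param x Query vector (length `M`); numeric for float engines, integer
#'   (quantized) for `wavefront`.
#' @param y Reference vector (length `N >= M`); same typing as `x`.
#' @param engine One of `"linear"`, `"oracle"`, `"wavefront"`.
#' @param fp [fp_config()]; required by the `wavefront` engine.
#' @param exclusion_window Minimum index distance from the best end for a
#'   candidate second-best end (default `2 * length(x)`, one query length
#'   of guard on each side).
#' @return An object of class `sdtw_result` with fields `score`, `end`
#'   (0-based), `second_score`, `second_end`, `engine`, and additionally
#'   `start`/`path` (oracle) or `steps`/`n_overflow` (wavefront).
#' @examples
#' sdtw(c(1, 2), c(0, 1, 2, 3))            # exact subsequence: score 0, end 2
#' sdtw(c(1, 3), c(0, 2, 4, 2), engine = "oracle")
#' @export
sdtw <- function(x, y, engine = c("linear", "oracle", "wavefront"),
                 fp = NULL, exclusion_window = NULL) {
  engine <- match.arg(engine)
  if (length(x) < 1 || length(y) < 1) {
    sqm_stop("query and reference must be non-empty", "sqm_size_error")
  }
  if (length(x) > length(y)) {
    sqm_stop("query length M must not exceed reference length N",
             "sqm_size_error")
  }
  if (is.null(exclusion_window)) exclusion_window <- 2L * length(x)
  res <- switch(engine,
    oracle = sdtw_oracle_cpp(as.numeric(x), as.numeric(y),
                             as.integer(exclusion_window)),
    linear = sdtw_linear_cpp(as.numeric(x), as.numeric(y),
                             as.integer(exclusion_window)),
    wavefront = {
      if (is.null(fp)) fp <- fp_config()
      stopifnot(inherits(fp, "fp_config"))
      sdtw_fixed_wave_cpp(as.integer(x), as.integer(y), fp$bits,
                          fp$overflow == "wraparound",
                          as.integer(exclusion_window))
    })
  res$engine <- engine
  structure(res, class = "sdtw_result")
}

#' Sequential fixed-point sDTW (linear-space, integer arithmetic)
#'
#' The straightforward column-by-column evaluation of the linear-space
#' algorithm in `bits`-wide integer arithmetic.  The wavefront engine is
#' bit-identical to this by construction; this entry point exists so that
#' equivalence can be checked and so the fixed-point semantics can be used
#' without the PE-chain scheduling model.
#'
#' @inheritParams sdtw
#' @param fp [fp_config()].
#' @return An `sdtw_result` (engine `"fixed_seq"`).
#' @export
sdtw_fixed_seq <- function(x, y, fp = fp_config(), exclusion_window = NULL) {
  if (length(x) > length(y) || length(x) < 1) {
    sqm_stop("need 1 <= M <= N", "sqm_size_error")
  }
  if (is.null(exclusion_window)) exclusion_window <- 2L * length(x)
  res <- sdtw_fixed_seq_cpp(as.integer(x), as.integer(y), fp$bits,
                            fp$overflow == "wraparound",
                            as.integer(exclusion_window))
  res$engine <- "fixed_seq"
  structure(res, class = "sdtw_result")
}

#' @export
print.sdtw_result <- function(x, ...) {
  cat(sprintf("<sdtw_result> engine '%s': score %g, end %d", x$engine,
              x$score, x$end))
  if (!is.null(x$start)) cat(sprintf(", start %d", x$start))
  if (!is.na(x$second_score)) {
    cat(sprintf(" (second best %g @ %d)", x$second_score, x$second_end))
  }
  cat("\n")
  if (!is.null(x$steps)) {
    cat(sprintf("  %d wavefront steps, %g overflow events\n", x$steps,
                x$n_overflow))
  }
  invisible(x)
}

#' Manhattan distance, optionally in fixed-point word-width arithmetic
#'
#' `|a - b|` elementwise.  With an [fp_config()], the subtraction and the
#' absolute value are both computed in the configured word width under the
#' configured overflow policy (so e.g. `|-32768 - 1|` wraps in 16-bit
#' wraparound mode exactly as a hardware accumulator would).
#'
#' @param a,b Numeric (or integer) vectors of equal length.
#' @param fp Optional [fp_config()] selecting fixed-point semantics.
#' @return Numeric (or integer) vector of distances; in fixed-point mode an
#'   attribute `n_overflow` counts overflow events.
#' @export
manhattan <- function(a, b, fp = NULL) {
  if (length(a) != length(b)) {
    sqm_stop("length mismatch", "sqm_size_error")
  }
  if (is.null(fp)) return(abs(a - b))
  stopifnot(inherits(fp, "fp_config"))
  r <- manhattan_fixed_cpp(as.integer(a), as.integer(b), fp$bits,
                           fp$overflow == "wraparound")
  structure(r$value, n_overflow = r$n_overflow)
}

#' Best and second-best minima of a score stream
#'
#' Finds the global minimum (smallest index on ties) and the best minimum
#' among positions farther than `exclusion_window` from it — the inputs to
#' the mapping-quality computation.  The guard window prevents the
#' runner-up from being the same alignment shifted by a few positions.
#'
#' @param values Numeric vector of last-row sDTW scores.
#' @param exclusion_window Minimum index distance (default 0).
#' @return List with `score`, `end` (0-based index), `second_score`,
#'   `second_end`; the second pair is `NA` when no position lies outside
#'   the window.
#' @export
best_and_second <- function(values, exclusion_window = 0L) {
  if (length(values) == 0) {
    sqm_stop("empty score stream", "sqm_size_error")
  }
  bi <- which.min(values)           # smallest index on ties
  eligible <- which(abs(seq_along(values) - bi) > exclusion_window)
  if (length(eligible) == 0) {
    si <- NA_integer_
    sv <- NA_real_
  } else {
    si <- eligible[which.min(values[eligible])]
    sv <- values[si]
  }
  list(score = values[bi], end = bi - 1L,
       second_score = sv,
       second_end = if (is.na(si)) NA_integer_ else si - 1L)
}
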