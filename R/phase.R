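#' Wrap values onto the unit phase circle
#'
#' Circadian phases are handled throughout the package in relative units: one
#' full cycle equals 1, so a phase lives in `[0, 1)` and a phase *shift* lives
#' in the principal interval `[-0.5, 0.5)`. `wrap_phase()` reduces any real
#' number modulo 1; `wrap_shift()` reduces a phase difference into
#' `[-0.5, 0.5)`, with the boundary convention that exactly +0.5 maps to -0.5
#' (half-open interval, deterministic for ties).
#'
#' @param x numeric vector of phases (cycles) or phase differences.
#' @return numeric vector of the same length, in `[0, 1)` for `wrap_phase()`
#'   and in `[-0.5, 0.5)` for `wrap_shift()`.
#' @examples
#' wrap_phase(c(-0.25, 1.25)) # 0.75 0.25
#' wrap_shift(c(0.75, -0.6, 0.5)) # -0.25 0.4 -0.5
#' @export
wrap_phase <- function(x) x - floor(x)

#' @rdname wrap_phase
#' @export
wrap_shift <- function(x) wrap_phase(x + 0.5) - 0.5

#' Circular distance between two phases
#'
#' Shortest distance around the unit circle, in cycle units (maximum 0.5).
#'
#' @param a,b phases in cycle units.
#' @return numeric vector of absolute circular distances.
#' @export
circ_dist <- function(a, b) abs(wrap_shift(a - b))
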