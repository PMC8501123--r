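#' Circular summary statistics on unit-cycle phases
#'
#' Phases in `[0, 1)` are mapped to angles by multiplication with `2*pi`. The
#' circular mean is the direction of the summed unit vectors, mapped back to
#' `[0, 1)`. The circular standard deviation is `sqrt(-2 * log(Rbar)) / (2*pi)`
#' in cycle units, where `Rbar` is the mean resultant length. When `Rbar` is
#' numerically zero the mean direction is undefined and `NA` is returned with
#' a warning.
#'
#' @param phases numeric vector of phases in cycle units (any real values are
#'   wrapped onto `[0, 1)` first).
#' @return `circular_mean()` and `circular_sd()` return a single number in
#'   cycle units; `circular_rbar()` the mean resultant length in `[0, 1]`.
#' @examples
#' circular_mean(c(0.9, 0.1)) # 0, not 0.5
#' circular_sd(rep(0.3, 5)) # 0
#' @export
circular_mean <- function(phases) {
  check_phases(phases)
  ang <- 2 * pi * phases
  s <- mean(sin(ang))
  c <- mean(cos(ang))
  if (sqrt(s^2 + c^2) < 1e-12) {
    warn("mean resultant length ~ 0: circular mean is undefined")
    return(NA_real_)
  }
  # zap cancellation residue so antipodal pairs give an exact mean direction
  if (abs(s) < 1e-12) s <- 0
  if (abs(c) < 1e-12) c <- 0
  wrap_phase(atan2(s, c) / (2 * pi))
}

#' @rdname circular_mean
#' @export
circular_rbar <- function(phases) {
  check_phases(phases)
  ang <- 2 * pi * phases
  sqrt(mean(sin(ang))^2 + mean(cos(ang))^2)
}

#' @rdname circular_mean
#' @export
circular_sd <- function(phases) {
  rbar <- min(circular_rbar(phases), 1) # guard fp overshoot above 1
  if (rbar < 1e-12) return(Inf)
  if (1 - rbar < 1e-12) return(0)
  sqrt(-2 * log(rbar)) / (2 * pi)
}

check_phases <- function(phases) {
  if (length(phases) == 0 || anyNA(phases)) {
    abort("`phases` must be non-empty and free of NA")
  }
  invisible(phases)
}

#' Circular-circular correlation
#'
#' Jammalamadaka-SenGupta circular correlation coefficient between two phase
#' vectors, with its large-sample normal-approximation p-value.
#'
#' @param phases,phases2 numeric vectors of phases in cycle units, equal
#'   length.
#' @return a tibble with columns `estimate`, `statistic` (asymptotic z) and
#'   `p.value` (two-sided).
#' @export
circular_corr <- function(phases, phases2) {
  check_phases(phases)
  check_phases(phases2)
  if (length(phases) != length(phases2)) abort("phase vectors must have equal length")
  n <- length(phases)
  a <- 2 * pi * phases
  b <- 2 * pi * phases2
  sa <- sin(a - 2 * pi * circular_mean(phases))
  sb <- sin(b - 2 * pi * circular_mean(phases2))
  denom <- sqrt(sum(sa^2) * sum(sb^2))
  if (denom < 1e-12) abort("degenerate input: no angular dispersion")
  rho <- sum(sa * sb) / denom
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * rho
  tibble(estimate = rho, statistic = z, p.value = 2 * pnorm(-abs(z)))
}

#' Circular-linear correlation
#'
#' Correlation between a phase and a linear covariate (e.g. pre-cue amplitude
#' vs phase shift), computed as the multiple correlation of the linear
#' variable on `(cos, sin)` of the angle, with the classical chi-squared
#' p-value (`n * r^2 ~ chisq(2)` under independence).
#'
#' @param phases numeric vector of phases in cycle units.
#' @param x numeric vector, same length.
#' @return a tibble with columns `estimate`, `statistic` and `p.value`.
#' @export
circ_lin_corr <- function(phases, x) {
  check_phases(phases)
  if (length(phases) != length(x)) abort("inputs must have equal length")
  n <- length(x)
  a <- 2 * pi * phases
  rxc <- stats::cor(x, cos(a)); rxs <- stats::cor(x, sin(a))
  rcs <- stats::cor(cos(a), sin(a))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r <- sqrt(max(r2, 0))
  stat <- n * r^2
  tibble(estimate = r, statistic = stat, p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Rayleigh test of phase uniformity
#'
#' Tests the null hypothesis that phases are uniformly distributed on the
#' circle, using the Rayleigh statistic with the standard finite-sample
#' corrected p-value approximation.
#'
#' @param phases numeric vector of phases in cycle units.
#' @return a tibble with columns `rbar`, `statistic` (Rayleigh Z) and
#'   `p.value`.
#' @export
rayleigh_test <- function(phases) {
  rbar <- circular_rbar(phases)
  n <- length(phases)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) - (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble(rbar = rbar, statistic = z, p.value = min(max(p, 0), 1))
}
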