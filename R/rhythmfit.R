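#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the observed mean; at most
#' 1 and possibly negative for fits worse than the mean.
#'
#' @param observed,fitted numeric vectors of equal length (>= 3).
#' @return a single number.
#' @export
rsquared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 3) {
    abort("observed and fitted must have equal length >= 3")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot < .Machine$double.eps) abort("degenerate input: zero total sum of squares")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Windowed cosine fit with an exhaustive period scan
#'
#' For every candidate period `tau` on the grid `seq(tau_min, tau_max,
#' tau_step)` the model `y ~ mesor + a*cos(2*pi*t/tau) + b*sin(2*pi*t/tau)`
#' is solved by linear least squares on the samples falling inside the
#' window (closed interval), and the `tau` maximizing R^2 wins (ties broken
#' toward the smaller period). The fitted amplitude is `sqrt(a^2 + b^2)` and
#' `peak_time` is the first time `>= window[1]` at which the fitted cosine
#' attains its maximum.
#'
#' @param tracks a [track_table()] of (typically detrended) traces, or any
#'   tibble with `cell_id`, `time_h`, `value`.
#' @param window numeric length-2, window in hours (closed interval).
#' @param tau_min,tau_max,tau_step period scan grid, hours.
#' @return a tibble with one row per cell: `cell_id`, `period`, `peak_time`,
#'   `amplitude`, `mesor`, `r2`, `window_start`, `window_end`.
#' @examples
#' tt <- track_table(data.frame(
#'   cell_id = "c1", time_h = 0:96,
#'   value = cos(2 * pi * (0:96) / 26)
#' ))
#' fit_cosine_scan(tt, window = c(24, 96))
#' @export
fit_cosine_scan <- function(tracks, window, tau_min = 20, tau_max = 32,
                            tau_step = 0.1) {
  stopifnot(length(window) == 2, window[1] < window[2])
  taus <- seq(tau_min, tau_max, by = tau_step)
  tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    dplyr::reframe(fit_cosine_window(.data$time_h, .data$value, window, taus)) |>
    ungroup()
}

fit_cosine_window <- function(t, y, window, taus) {
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) abort("window lies outside the trace span")
  tw <- t[sel]
  yw <- y[sel]
  if (length(tw) < 4) abort("window holds too few samples for a cosine fit")
  ss_tot <- sum((yw - mean(yw))^2)
  if (ss_tot < .Machine$double.eps) abort("degenerate (zero-variance) window")

  best <- list(r2 = -Inf)
  for (tau in taus) {
    w <- 2 * pi / tau
    X <- cbind(1, cos(w * tw), sin(w * tw))
    fit <- .lm.fit(X, yw)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 > best$r2) best <- list(r2 = r2, tau = tau, coef = fit$coefficients)
  }
  a <- best$coef[2]; b <- best$coef[3]
  amp <- sqrt(a^2 + b^2)
  # y = mesor + amp * cos(w t - phi), peak where w t = phi (mod 2 pi)
  phi <- atan2(b, a)
  t_peak0 <- phi / (2 * pi) * best$tau
  peak_time <- window[1] + wrap_phase((t_peak0 - window[1]) / best$tau) * best$tau
  tibble(period = best$tau, peak_time = peak_time, amplitude = amp,
         mesor = best$coef[1], r2 = best$r2,
         window_start = window[1], window_end = window[2])
}

#' Rhythmicity call on cosine fits
#'
#' A fit counts as rhythmic when its R^2 strictly exceeds `r2_min` (default
#' 0.5); exactly 0.5 is not rhythmic.
#'
#' @param fits a fit tibble from [fit_cosine_scan()] (or anything with an
#'   `r2` column), or a bare numeric vector of R^2 values.
#' @param r2_min threshold.
#' @return logical vector.
#' @export
is_rhythmic <- function(fits, r2_min = 0.5) {
  r2 <- if (is.numeric(fits)) fits else fits$r2
  r2 > r2_min
}

#' Per-cycle peak-time agreement between fit and raw data
#'
#' Diagnostic for the phase estimate: each fitted peak inside the window is
#' compared to the nearest local maximum of the raw trace within half a
#' period. On well-behaved data the deviations scatter around zero with an
#' SD below ~1 h; the check is a soft diagnostic, not a gate. Cycles whose
#' raw trace has no local maximum in range are reported with `NA` deviation.
#'
#' @param tracks raw (not detrended) traces; tibble with `cell_id`,
#'   `time_h`, `value`.
#' @param fits fit tibble from [fit_cosine_scan()].
#' @return a tibble with one row per (cell, cycle): `cell_id`, `cycle`,
#'   `fit_peak`, `raw_peak`, `deviation_h`.
#' @export
peak_phase_qc <- function(tracks, fits) {
  tr_split <- split(as_tibble(tracks), tracks$cell_id)
  rows <- pmap(fits, function(cell_id, period, peak_time, window_start,
                               window_end, ...) {
    tr <- tr_split[[cell_id]]
    peaks <- seq(peak_time, window_end, by = period)
    peaks <- peaks[peaks >= window_start]
    sel <- tr$time_h >= window_start & tr$time_h <= window_end
    tw <- tr$time_h[sel]; yw <- tr$value[sel]
    locmax <- tw[local_maxima(yw)]
    map2(peaks, seq_along(peaks), function(p, k) {
      cand <- locmax[abs(locmax - p) <= period / 2]
      # the corresponding raw maximum is the highest one in range
      raw <- if (length(cand) == 0) NA_real_ else
        cand[which.max(yw[match(cand, tw)])]
      tibble(cell_id = cell_id, cycle = k, fit_peak = p, raw_peak = raw,
             deviation_h = raw - p)
    }) |> list_rbind()
  })
  list_rbind(rows)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Instantaneous amplitude over the last pre-cue cycle
#'
#' Half the peak-to-trough range of the (detrended) signal over the last full
#' fitted cycle ending at or before the cue; used for the amplitude-vs-shift
#' diagnostic. The fitted harmonic amplitude is available from
#' [fit_cosine_scan()] as an alternative definition.
#'
#' @param tracks detrended traces.
#' @param fits before-window fit tibble.
#' @param cue_time hours.
#' @return a tibble `cell_id`, `amplitude_pre_cue`.
#' @export
amplitude_before_cue <- function(tracks, fits, cue_time) {
  tr_split <- split(as_tibble(tracks), tracks$cell_id)
  rows <- pmap(fits, function(cell_id, period, ...) {
    tr <- tr_split[[cell_id]]
    lo <- cue_time - period
    if (lo < min(tr$time_h)) abort("no complete cycle before the cue")
    sel <- tr$time_h >= lo & tr$time_h <= cue_time
    yw <- tr$value[sel]
    tibble(cell_id = cell_id, amplitude_pre_cue = (max(yw) - min(yw)) / 2)
  })
  list_rbind(rows)
}
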