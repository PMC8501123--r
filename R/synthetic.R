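#' Parametric ground-truth resetting map
#'
#' Describes how a one-time cue remaps a cell's clock phase, in one of the
#' three canonical topologies:
#' * `"none"`: `new = wrap(old + eps)` — no response.
#' * `"type1"` (weak resetting, PTC mean slope 1):
#'   `new = wrap(old + A * sin(2*pi*(old - psi)) + eps)`. The constraint
#'   `2*pi*A < 1` keeps the map monotone (a degree-1 circle map).
#' * `"type0"` (strong resetting, PTC mean slope 0):
#'   `new = wrap(target + B * sin(2*pi*(old - psi)) + eps)` — the new phase
#'   clusters at the attractor `target` regardless of the old phase.
#'
#' `eps ~ Normal(0, phase_noise_sd)` models cycle-to-cycle phase stochasticity.
#'
#' @param kind one of `"none"`, `"type1"`, `"type0"`.
#' @param A PRC amplitude in cycle units (type-1).
#' @param psi reference phase in `[0, 1)`.
#' @param target attractor phase in `[0, 1)` (type-0).
#' @param B residual modulation amplitude around the attractor (type-0).
#' @param phase_noise_sd SD of the additive phase noise, cycle units.
#' @return a named list of class `response_map`.
#' @examples
#' apply_resetting(0.25, response_map("type1", A = 0.1, psi = 0)) # 0.35
#' @export
response_map <- function(kind = c("none", "type1", "type0"),
                         A = 0.15, psi = 0.6, target = 0.3, B = 0.05,
                         phase_noise_sd = 0) {
  kind <- match.arg(kind)
  if (kind == "type1" && 2 * pi * A >= 1) {
    abort("type-1 map requires 2*pi*A < 1 (monotone PTC)")
  }
  if (phase_noise_sd < 0 || A < 0 || B < 0) abort("amplitudes and noise SD must be >= 0")
  structure(list(kind = kind, A = A, psi = wrap_phase(psi),
                 target = wrap_phase(target), B = B,
                 phase_noise_sd = phase_noise_sd),
            class = "response_map")
}

#' Apply a resetting map to old phases
#'
#' Vectorized evaluation of a [response_map()]; with `phase_noise_sd = 0`
#' the map is deterministic.
#'
#' @param old_phase numeric vector of phases in `[0, 1)`.
#' @param map a [response_map()].
#' @return numeric vector of new phases in `[0, 1)`.
#' @export
apply_resetting <- function(old_phase, map) {
  if (!inherits(map, "response_map")) abort("`map` must be a response_map")
  old <- wrap_phase(old_phase)
  eps <- if (map$phase_noise_sd > 0) rnorm(length(old), 0, map$phase_noise_sd) else 0
  new <- switch(map$kind,
    none = old + eps,
    type1 = old + map$A * sin(2 * pi * (old - map$psi)) + eps,
    type0 = map$target + map$B * sin(2 * pi * (old - map$psi)) + eps
  )
  wrap_phase(new)
}

#' Simulation configuration for a synthetic reporter population
#'
#' Defaults emulate the statistical structure of a 9-day, 1-h-interval
#' recording of a non-synchronized fibroblast reporter population: initial
#' phases uniform on the cycle, cell-autonomous periods of 26 +/- 1 h that
#' drift to ~25 h by the end of the recording, a slow (>= 72 h timescale)
#' logistic baseline trend with a gradual gain change, and additive Gaussian
#' measurement noise. The cue fires at 108 h (4.5 days).
#'
#' @param n_cells number of simulated cells.
#' @param duration recording length, hours.
#' @param sampling_interval hours between frames.
#' @param period_mean,period_sd period distribution at recording start,
#'   hours; draws are truncated to `[20, 32]`.
#' @param period_drift linear drift of the instantaneous period, hours per
#'   day (negative = shortening). Default -1/9 h/day (1 h over 9 days).
#' @param amplitude_mean,amplitude_sd oscillation amplitude distribution,
#'   a.u. (draws truncated below at 0.1 * mean).
#' @param trend_base,trend_rise,trend_midpoint,trend_scale slow logistic
#'   baseline: `trend_base + trend_rise * plogis((t - midpoint)/scale)`;
#'   `trend_scale` >= 72 h keeps the trend well below the detrending band.
#' @param gain_change relative linear change of oscillation amplitude across
#'   the recording (e.g. -0.2 = 20 % fade).
#' @param measurement_noise_sd additive Gaussian noise SD, a.u.
#' @param cue_time hours of the one-time intervention.
#' @param response a [response_map()].
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 400, duration = 216, sampling_interval = 1,
                       period_mean = 26, period_sd = 1, period_drift = -1 / 9,
                       amplitude_mean = 1, amplitude_sd = 0.2,
                       trend_base = 5, trend_rise = 1,
                       trend_midpoint = 108, trend_scale = 72,
                       gain_change = -0.2,
                       measurement_noise_sd = 0.2,
                       cue_time = 108,
                       response = response_map("none"),
                       seed = 1L) {
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (period_sd < 0 || amplitude_sd < 0 || measurement_noise_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (cue_time <= 0 || cue_time >= duration) abort("cue_time must lie inside the recording span")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a tracked single-cell reporter population
#'
#' Generates one [track_table()] plus its ground truth. Per cell: initial
#' phase `~ Uniform[0,1)`, start period `~ Normal(period_mean, period_sd)`
#' truncated to `[20, 32]` h, amplitude `~ Normal` truncated positive. The
#' instantaneous period drifts linearly in time,
#' `tau(t) = tau0 + period_drift * t / 24`, and the oscillation phase is its
#' integrated instantaneous frequency `Phi(t) = phi0 + int_0^t ds / tau(s)`
#' (closed form). The trace is
#' `trend(t) + gain(t) * amplitude * cos(2*pi*Phi(t)) + noise`. At
#' `cue_time` the phase is remapped by [apply_resetting()] as an
#' instantaneous jump.
#'
#' The ground truth records, per cell, the drawn parameters, the true phase
#' at the cue before (`old_phase_true`) and after (`new_phase_true`) the
#' jump, and the effective mean periods over the before/after fit windows
#' (24-96 h and 120-192 h by default conventions),
#' `tau_w = |w| / (Phi(w_end) - Phi(w_start))`.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_population`: list with elements `tracks`
#'   (a `track_table`) and `truth` (a tibble keyed by `cell_id`), plus the
#'   config.
#' @export
simulate_population <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cells
  times <- seq(0, cfg$duration, by = cfg$sampling_interval)

  phi0 <- runif(n)
  tau0 <- rnorm_trunc(n, cfg$period_mean, cfg$period_sd, 20, 32)
  amp <- rnorm_trunc(n, cfg$amplitude_mean, cfg$amplitude_sd,
                     0.1 * cfg$amplitude_mean, Inf)
  r <- cfg$period_drift / 24 # h per h

  # integrated instantaneous frequency from 0 to t for start period tau0
  phase_int <- function(t, tau0) {
    if (abs(r) < 1e-12) t / tau0 else log1p(r * t / tau0) / r
  }

  old_true <- wrap_phase(phi0 + vapply(tau0, function(tt) phase_int(cfg$cue_time, tt), 0))
  new_true <- apply_resetting(old_true, cfg$response)
  jump <- wrap_shift(new_true - old_true)

  trend <- cfg$trend_base + cfg$trend_rise * stats::plogis((times - cfg$trend_midpoint) / cfg$trend_scale)
  gain <- 1 + cfg$gain_change * times / cfg$duration

  traces <- vector("list", n)
  ids <- sprintf("cell%04d", seq_len(n))
  for (i in seq_len(n)) {
    phi <- phi0[i] + phase_int(times, tau0[i])
    phi <- phi + jump[i] * (times >= cfg$cue_time)
    y <- trend + gain * amp[i] * cos(2 * pi * phi)
    if (cfg$measurement_noise_sd > 0) y <- y + rnorm(length(times), 0, cfg$measurement_noise_sd)
    traces[[i]] <- tibble(cell_id = ids[i], time_h = times, value = y)
  }

  win_tau <- function(w) {
    span <- w[2] - w[1]
    vapply(tau0, function(tt) span / (phase_int(w[2], tt) - phase_int(w[1], tt)), 0)
  }
  truth <- tibble(
    cell_id = ids, phase0 = phi0, tau0 = tau0, amplitude = amp,
    old_phase_true = old_true, new_phase_true = new_true,
    shift_true = jump,
    tau_before_true = win_tau(c(24, 96)),
    tau_after_true = win_tau(c(120, 192))
  )

  tracks <- track_table(list_rbind(traces), cue_time = cfg$cue_time,
                        sampling_interval = cfg$sampling_interval,
                        treatment = cfg$response$kind)
  structure(list(tracks = tracks, truth = truth, config = cfg),
            class = "sim_population")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    guard <- guard + 1
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate phase pairs directly from a resetting map
#'
#' Pair-level shortcut that skips trace synthesis and fitting: old phases are
#' drawn uniformly, new phases come from [apply_resetting()]. Useful for
#' statistical calibration studies where only the PTC-level behaviour
#' matters; the trace-to-pair stage is exercised separately by the full
#' simulator.
#'
#' @param n number of cells (pairs).
#' @param map a [response_map()].
#' @param tau_before,tau_after nominal periods recorded in the pair table,
#'   hours.
#' @param seed optional integer seed.
#' @return a `ptc_dataset` tibble (see [filter_pairs()]) with perfect fit
#'   qualities, flagged as filtered.
#' @export
simulate_phase_pairs <- function(n, map = response_map("none"),
                                 tau_before = 26, tau_after = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  old <- runif(n)
  new <- apply_resetting(old, map)
  pairs <- tibble(
    cell_id = sprintf("cell%04d", seq_len(n)),
    old_phase = old, new_phase = new,
    shift = wrap_shift(new - old),
    tau_before = tau_before, tau_after = tau_after,
    r2_before = 1, r2_after = 1
  )
  new_ptc_dataset(pairs, treatment = map$kind, filtered = TRUE,
                  filter_spec = list(r2_min = 0, tau_bounds = c(20, 32)))
}
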