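# shared fixture builders; everything is generated in code at test time

# a clean cosine trace on the standard 9-day grid
cosine_track <- function(period = 26, duration = 216, amplitude = 1,
                         trend = function(t) 0, phase0 = 0, cue = 108,
                         id = "c1", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1)
  y <- trend(t) + amplitude * cos(2 * pi * (t / period + phase0))
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  track_table(data.frame(cell_id = id, time_h = t, value = y), cue_time = cue)
}

# several cosine traces with given periods/phases in one table
cosine_population <- function(periods, phases = rep(0, length(periods)),
                              duration = 216, cue = 108, noise_sd = 0,
                              seed = 1) {
  set.seed(seed)
  t <- seq(0, duration, by = 1)
  df <- purrr::imap(periods, function(p, i) {
    y <- cos(2 * pi * (t / p + phases[i])) + rnorm(length(t), 0, noise_sd)
    data.frame(cell_id = sprintf("c%03d", i), time_h = t, value = y)
  }) |> purrr::list_rbind()
  track_table(df, cue_time = cue)
}

# bare phase-pair tibble as a ptc_dataset (for direct model fitting)
pairs_dataset <- function(old, new, tau_before = 26, tau_after = 25,
                          r2 = 0.95) {
  ds <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_along(old)),
    old_phase = old, new_phase = wrap_phase(new),
    shift = wrap_shift(new - old),
    tau_before = tau_before, tau_after = tau_after,
    r2_before = r2, r2_after = r2
  )
  filter_pairs(ds, r2_min = 0, tau_bounds = c(20, 32))
}

# reference truncated-window running mean (independent of the package's)
running_mean_ref <- function(y, k) {
  n <- length(y)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) mean(y[max(1, i - h):min(n, i + h)]), 0)
}
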