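#' Keep only tracks spanning the whole recording
#'
#' Cells must be observed at every timepoint of the common grid to enter the
#' PTC analysis; partial tracks are dropped and counted. The kept/dropped
#' counts feed the per-stage funnel report.
#'
#' @param tracks a [track_table()].
#' @return a `track_table` restricted to full-span cells, with an attribute
#'   `span_report`: tibble of `cell_id`, `n_obs`, `kept`.
#' @export
select_full_span <- function(tracks) {
  grid_n <- dplyr::n_distinct(tracks$time_h)
  rep_tbl <- tracks |>
    as_tibble() |>
    count(.data$cell_id, name = "n_obs") |>
    mutate(kept = .data$n_obs == grid_n)
  keep <- rep_tbl$cell_id[rep_tbl$kept]
  if (length(keep) == 0) warn("no full-span tracks remain")
  out <- restore_track_attrs(filter(as_tibble(tracks), .data$cell_id %in% keep), tracks)
  attr(out, "span_report") <- rep_tbl
  out
}

#' Z-score detrending with a running-average trend
#'
#' For each trace, a trend is estimated as the running average over a
#' `window_h`-hour window (48 h by default, long enough to pass circadian
#' oscillations through to the residual), subtracted, and the residual is
#' divided by a standard deviation: by default the SD of the trend-subtracted
#' residual, so outputs are unit-SD residuals (`sd_mode = "raw"` divides by
#' the raw-track SD instead). Window edges use shrinking (truncated) windows;
#' the window is converted to samples via the sampling interval and forced to
#' an odd count by rounding up.
#'
#' Essentially flat traces (residual SD below `1e-10` of the raw SD, or zero)
#' raise a degenerate-trace error when given a single trace, and are dropped
#' with a warning when detrending a whole table.
#'
#' @param tracks a [track_table()] (or any tibble with `cell_id`, `time_h`,
#'   `value`).
#' @param window_h trend window, hours.
#' @param sd_mode `"residual"` or `"raw"`.
#' @return a `track_table` whose `value` column holds the detrended signal
#'   (attribute `detrended = TRUE`); dropped degenerate cells listed in
#'   attribute `degenerate_cells`.
#' @export
detrend_zscore <- function(tracks, window_h = 48, sd_mode = c("residual", "raw")) {
  sd_mode <- match.arg(sd_mode)
  dt <- sampling_interval(tracks) %||% 1
  if (is.na(dt)) dt <- 1
  split_tr <- split(as_tibble(tracks), tracks$cell_id)
  bad <- character()
  out <- lapply(split_tr, function(tr) {
    z <- try(detrend_vector(tr$value, window_h, dt, sd_mode), silent = TRUE)
    if (inherits(z, "try-error")) {
      bad <<- c(bad, tr$cell_id[1])
      return(NULL)
    }
    tr$value <- z
    tr
  })
  if (length(bad) == length(split_tr)) {
    abort("degenerate-trace error: all traces are flat (zero residual SD)")
  }
  if (length(bad) > 0) {
    warn(paste0("degenerate (flat) trace(s) dropped: ", paste(bad, collapse = ", ")))
  }
  res <- restore_track_attrs(list_rbind(out[!vapply(out, is.null, TRUE)]), tracks)
  attr(res, "detrended") <- TRUE
  attr(res, "degenerate_cells") <- bad
  res
}

# running mean with truncated edge windows, O(n) via cumulative sums
running_mean <- function(y, k) {
  n <- length(y)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

detrend_vector <- function(y, window_h, dt, sd_mode) {
  k <- ceiling(window_h / dt)
  if (k %% 2 == 0) k <- k + 1
  if (length(y) <= k) abort("trace shorter than the detrending window")
  resid <- y - running_mean(y, k)
  s <- if (sd_mode == "residual") sd(resid) else sd(y)
  raw_scale <- max(sd(y), 1)
  if (!is.finite(s) || s < 1e-10 * raw_scale) {
    abort("degenerate-trace error: residual SD below machine tolerance")
  }
  resid / s
}
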