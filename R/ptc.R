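#' Tau-independent old phase (TIPA)
#'
#' The pre-cue fit gives the clock's relative phase at the cue,
#' `theta = ((cue_time - peak_time_before) mod tau_before) / tau_before`.
#' Because the period usually differs between the two fit windows, the
#' pre-cue fit is virtually extended from this phase onward with the
#' *after* period (the "null" curve): its first post-cue peak falls at
#' `cue_time + (1 - theta) * tau_after`. Both the old and the new phase are
#' thereby expressed on cosines sharing one period, making the phase shift
#' period-independent.
#'
#' All arguments are vectorized over cells.
#'
#' @param peak_time_before first fitted peak of the before-window fit, hours.
#' @param tau_before,tau_after fitted periods, hours (must be positive).
#' @param cue_time hours of the intervention.
#' @return a tibble with columns `old_phase` (in `[0,1)`) and
#'   `expected_peak_time` (hours, the null curve's first post-cue peak).
#' @examples
#' tipa_old_phase(90, 26, 24, 108) # old phase 18/26, peak 115.385 h
#' @export
tipa_old_phase <- function(peak_time_before, tau_before, tau_after, cue_time) {
  if (any(tau_before <= 0) || any(tau_after <= 0)) abort("periods must be positive")
  theta <- wrap_phase((cue_time - peak_time_before) / tau_before)
  tibble(old_phase = theta,
         expected_peak_time = cue_time + (1 - theta) * tau_after)
}

#' New phase from the after-window fit
#'
#' The after-window cosine's phase at the cue: equivalently, its first
#' post-cue peak projected back to the cue by whole periods,
#' `new_phase = ((cue_time - peak_time_after) mod tau_after) / tau_after`.
#'
#' @param peak_time_after first fitted peak of the after-window fit, hours.
#' @param tau_after fitted after period, hours.
#' @param cue_time hours.
#' @return numeric vector of new phases in `[0, 1)`.
#' @export
new_phase_from_after_fit <- function(peak_time_after, tau_after, cue_time) {
  if (any(tau_after <= 0)) abort("periods must be positive")
  wrap_phase((cue_time - peak_time_after) / tau_after)
}

#' Per-cell old/new phase pairs
#'
#' Joins before- and after-window fits by cell and composes
#' [tipa_old_phase()] with [new_phase_from_after_fit()]. The shift is
#' `wrap(new - old)` in `[-0.5, 0.5)`, with phase *advance* positive (the
#' clock sits further along its cycle after the cue).
#'
#' @param before_fits,after_fits fit tibbles from [fit_cosine_scan()] for
#'   the two windows.
#' @param cue_time hours.
#' @return a tibble with one row per cell present in both fits: `cell_id`,
#'   `old_phase`, `new_phase`, `shift`, `tau_before`, `tau_after`,
#'   `r2_before`, `r2_after`.
#' @export
make_phase_pairs <- function(before_fits, after_fits, cue_time) {
  joined <- dplyr::inner_join(
    rename(before_fits, tau_before = "period", peak_before = "peak_time",
           r2_before = "r2"),
    rename(after_fits, tau_after = "period", peak_after = "peak_time",
           r2_after = "r2"),
    by = "cell_id", suffix = c("_b", "_a")
  )
  tipa <- tipa_old_phase(joined$peak_before, joined$tau_before,
                         joined$tau_after, cue_time)
  new <- new_phase_from_after_fit(joined$peak_after, joined$tau_after, cue_time)
  tibble(
    cell_id = joined$cell_id,
    old_phase = tipa$old_phase,
    new_phase = new,
    shift = wrap_shift(new - tipa$old_phase),
    tau_before = joined$tau_before,
    tau_after = joined$tau_after,
    r2_before = joined$r2_before,
    r2_after = joined$r2_after
  )
}

new_ptc_dataset <- function(pairs, treatment = "untreated", dose = NA_real_,
                            filtered = FALSE, filter_spec = NULL,
                            funnel = NULL) {
  out <- as_tibble(pairs)
  attr(out, "treatment") <- treatment
  attr(out, "dose") <- dose
  attr(out, "filtered") <- filtered
  attr(out, "filter_spec") <- filter_spec
  attr(out, "funnel") <- funnel
  class(out) <- unique(c("ptc_dataset", class(out)))
  out
}

#' @export
print.ptc_dataset <- function(x, ...) {
  cat(sprintf("<ptc_dataset> %d phase pairs | %s%s | filtered: %s\n",
              nrow(x), attr(x, "treatment"),
              if (!is.na(attr(x, "dose") %||% NA)) paste0(" @ ", attr(x, "dose")) else "",
              isTRUE(attr(x, "filtered"))))
  NextMethod()
}

#' Quality filter for phase pairs
#'
#' Keeps pairs whose fits are rhythmic in *both* windows (`R^2 > r2_min`)
#' and whose periods both lie inside `tau_bounds` (inclusive at 22 and 29 h:
#' the exclusion rule is period > 29 or < 22). Per-criterion dropped counts
#' are recorded.
#'
#' @param pairs tibble from [make_phase_pairs()].
#' @param r2_min rhythmicity threshold (strict inequality).
#' @param tau_bounds accepted period range, hours, inclusive.
#' @param treatment,dose labels stored on the dataset.
#' @return a `ptc_dataset` tibble of kept pairs; attributes `filter_spec`
#'   (thresholds used) and `filter_report` (kept/dropped counts per
#'   criterion).
#' @export
filter_pairs <- function(pairs, r2_min = 0.5, tau_bounds = c(22, 29),
                         treatment = "untreated", dose = NA_real_) {
  ok_r2 <- pairs$r2_before > r2_min & pairs$r2_after > r2_min
  ok_tau <- pairs$tau_before >= tau_bounds[1] & pairs$tau_before <= tau_bounds[2] &
    pairs$tau_after >= tau_bounds[1] & pairs$tau_after <= tau_bounds[2]
  report <- tibble(
    n_input = nrow(pairs),
    n_fail_r2 = sum(!ok_r2),
    n_fail_tau = sum(ok_r2 & !ok_tau),
    n_kept = sum(ok_r2 & ok_tau)
  )
  new_ptc_dataset(pairs[ok_r2 & ok_tau, , drop = FALSE],
                  treatment = treatment, dose = dose, filtered = TRUE,
                  filter_spec = list(r2_min = r2_min, tau_bounds = tau_bounds),
                  funnel = NULL) |>
    structure(filter_report = report)
}

#' Assemble a PTC dataset from tracked traces
#'
#' End-to-end composition: full-span selection, z-score detrending, cosine
#' fitting in the before and after windows, rhythmicity gating and the
#' period filter, yielding the filtered phase-pair dataset together with a
#' per-stage funnel of cell counts.
#'
#' @param tracks a [track_table()] with a cue time set.
#' @param config a [ptc_config()].
#' @return a `ptc_dataset` with attribute `funnel` (tibble of stage, n).
#'   Fewer than `config$min_pairs` pairs raises an under-powered warning.
#' @export
assemble_ptc <- function(tracks, config = ptc_config()) {
  if (is.na(cue_time(tracks))) abort("tracks carry no cue_time")
  n0 <- dplyr::n_distinct(tracks$cell_id)
  full <- select_full_span(tracks)
  n1 <- dplyr::n_distinct(full$cell_id)
  det <- detrend_zscore(full, window_h = config$detrend_window_h,
                        sd_mode = config$sd_mode)
  n2 <- dplyr::n_distinct(det$cell_id)
  fb <- fit_cosine_scan(det, config$before_window, config$tau_min,
                        config$tau_max, config$tau_step)
  fa <- fit_cosine_scan(det, config$after_window, config$tau_min,
                        config$tau_max, config$tau_step)
  rhythmic <- intersect(fb$cell_id[is_rhythmic(fb, config$r2_min)],
                        fa$cell_id[is_rhythmic(fa, config$r2_min)])
  n3 <- length(rhythmic)
  pairs <- make_phase_pairs(fb, fa, cue_time(tracks))
  ds <- filter_pairs(pairs, r2_min = config$r2_min,
                     tau_bounds = config$tau_bounds,
                     treatment = attr(tracks, "treatment"))
  funnel <- tibble(
    stage = c("tracked", "full_span", "detrended", "rhythmic_both", "filtered"),
    n = c(n0, n1, n2, n3, nrow(ds))
  )
  attr(ds, "funnel") <- funnel
  if (nrow(ds) < config$min_pairs) {
    warn(sprintf("under-powered PTC: %d pairs (< %d)", nrow(ds), config$min_pairs))
  }
  ds
}

#' Funnel report of an assembled PTC
#'
#' @param dataset a `ptc_dataset` from [assemble_ptc()].
#' @return tibble of per-stage cell counts.
#' @export
funnel_report <- function(dataset) attr(dataset, "funnel")

#' Phase-plane binning across doses
#'
#' Bins old phases on `[0, 1)` into fixed-width bins (0.05 by default, 20
#' bins) and reports the circular-mean new phase per (dose, bin); empty bins
#' are `NA`. The result is the long form of the dose-by-old-phase heat map
#' used to locate singularity neighbourhoods.
#'
#' @param datasets a single `ptc_dataset` or a list of them ordered by dose.
#' @param doses numeric vector of doses (recycled from dataset attributes if
#'   absent).
#' @param bin bin width in cycle units.
#' @return tibble `dose`, `old_bin` (bin center), `new_phase_mean`, `n`.
#' @export
bin_phase_plane <- function(datasets, doses = NULL, bin = 0.05) {
  if (inherits(datasets, "ptc_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1) abort("need at least one dataset")
  if (is.null(doses)) {
    doses <- map_dbl(datasets, ~ attr(.x, "dose") %||% NA_real_)
    if (anyNA(doses)) doses <- seq_along(datasets)
  }
  breaks <- seq(0, 1, by = bin)
  centers <- head(breaks, -1) + bin / 2
  rows <- map2(datasets, doses, function(ds, dose) {
    idx <- findInterval(wrap_phase(ds$old_phase), breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    tibble(old_bin = centers,
           dose = dose,
           new_phase_mean = map_dbl(seq_along(centers), function(b) {
             ph <- ds$new_phase[idx == b]
             if (length(ph) == 0) NA_real_ else circular_mean(ph)
           }),
           n = map_dbl(seq_along(centers), function(b) sum(idx == b)))
  })
  list_rbind(rows)[, c("dose", "old_bin", "new_phase_mean", "n")]
}

#' Double-plotted coordinates for PTC/PRC display
#'
#' Duplicates each point one cycle to the right (and, for the PTC, one cycle
#' up), the conventional way of displaying circular phase data. Display
#' helper only; fitting and statistics never use the duplicated points.
#'
#' @param dataset a `ptc_dataset`.
#' @param type `"ptc"` (new phase on y) or `"prc"` (shift on y).
#' @return tibble `old_phase`, `y`, `copy`.
#' @export
double_plot <- function(dataset, type = c("ptc", "prc")) {
  type <- match.arg(type)
  y <- if (type == "ptc") dataset$new_phase else dataset$shift
  base <- tibble(old_phase = dataset$old_phase, y = y, copy = FALSE)
  dup <- tibble(old_phase = dataset$old_phase + 1,
                y = if (type == "ptc") y + 1 else y, copy = TRUE)
  bind_rows(base, dup)
}
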