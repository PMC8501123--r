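#' Build a track table from a long data frame
#'
#' A track table is the package's central container for tracked single-cell
#' reporter traces: a tibble in long form with one row per cell and timepoint
#' and columns `cell_id`, `time_h` (hours from recording start) and `value`
#' (background-corrected reporter intensity, arbitrary units). Experiment
#' metadata travels as attributes: `cue_time` (hours of the one-time
#' intervention), `sampling_interval` (hours between frames), `treatment` and
#' `well_id` labels.
#'
#' All traces must share one common time grid; `validate_track_table()`
#' enforces this together with strictly increasing times and absence of
#' internal gaps, reporting offending `cell_id`s.
#'
#' @param df data frame with columns `cell_id`, `time_h`, `value`.
#' @param cue_time hours from recording start of the intervention, or `NA` if
#'   the recording has no cue. Must lie strictly inside the recorded span.
#' @param sampling_interval hours between consecutive frames (default 1).
#' @param treatment,well_id optional labels.
#' @return a `track_table`: a tibble sorted by cell and time, with metadata
#'   attributes.
#' @examples
#' tt <- track_table(
#'   data.frame(cell_id = rep("c1", 5), time_h = 0:4, value = sin(0:4)),
#'   cue_time = 2
#' )
#' cue_time(tt)
#' @export
track_table <- function(df, cue_time = NA_real_, sampling_interval = 1,
                        treatment = "untreated", well_id = "well1") {
  need <- c("cell_id", "time_h", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(df)[need]
  out$cell_id <- as.character(out$cell_id)
  out <- arrange(out, .data$cell_id, .data$time_h)
  attr(out, "cue_time") <- as.numeric(cue_time)
  attr(out, "sampling_interval") <- as.numeric(sampling_interval)
  attr(out, "treatment") <- treatment
  attr(out, "well_id") <- well_id
  class(out) <- c("track_table", class(out))
  validate_track_table(out)
}

#' @rdname track_table
#' @param x a `track_table`.
#' @export
cue_time <- function(x) attr(x, "cue_time")

#' @rdname track_table
#' @export
sampling_interval <- function(x) attr(x, "sampling_interval")

#' @rdname track_table
#' @export
validate_track_table <- function(x) {
  if (nrow(x) == 0) return(x)
  dup <- x[duplicated(x[c("cell_id", "time_h")]), ]
  if (nrow(dup) > 0) {
    abort(paste0("duplicated (cell_id, time_h) rows for cell(s): ",
                 paste(unique(dup$cell_id), collapse = ", ")))
  }
  if (anyNA(x$value) || anyNA(x$time_h)) {
    bad <- unique(x$cell_id[is.na(x$value) | is.na(x$time_h)])
    abort(paste0("missing values inside traces for cell(s): ",
                 paste(bad, collapse = ", ")))
  }
  grid <- sort(unique(x$time_h))
  ct <- cue_time(x)
  if (!is.na(ct) && (ct <= min(grid) || ct >= max(grid))) {
    abort("cue_time must lie strictly inside the recorded span")
  }
  x
}

#' @export
print.track_table <- function(x, ...) {
  ncell <- dplyr::n_distinct(x$cell_id)
  cat(sprintf(
    "<track_table> %d cells x %d timepoints | cue %s h | dt %g h | %s / %s\n",
    ncell, dplyr::n_distinct(x$time_h), format(cue_time(x)),
    sampling_interval(x), attr(x, "treatment"), attr(x, "well_id")
  ))
  NextMethod()
}

restore_track_attrs <- function(out, template) {
  attr(out, "cue_time") <- attr(template, "cue_time")
  attr(out, "sampling_interval") <- attr(template, "sampling_interval")
  attr(out, "treatment") <- attr(template, "treatment")
  attr(out, "well_id") <- attr(template, "well_id")
  if (!inherits(out, "track_table")) class(out) <- c("track_table", class(out))
  out
}

#' Column dialect for tracked-object tables
#'
#' Tracked-object exports from imaging pipelines name their columns
#' differently; a dialect maps the three required concepts onto concrete
#' column names. `time_unit = "frames"` converts an integer frame index to
#' hours via `sampling_interval` (frame 0 = 0 h).
#'
#' @param cell,time,value column names in the delimited file.
#' @param time_unit `"hours"` or `"frames"`.
#' @return a named list of class `track_dialect`.
#' @export
track_dialect <- function(cell = "cell_id", time = "time_h", value = "intensity",
                          time_unit = c("hours", "frames")) {
  structure(list(cell = cell, time = time, value = value,
                 time_unit = match.arg(time_unit)),
            class = "track_dialect")
}

#' Read a tracked-object table from delimited text
#'
#' Ingests a per-cell, per-timepoint intensity table (CSV) into a
#' [track_table()]. Traces with internal gaps (a missing timepoint between
#' their first and last observation, relative to the common grid) are
#' excluded and listed in the `gap_report` attribute; ingest never silently
#' drops rows.
#'
#' @param path file path of a delimited text table.
#' @param dialect a [track_dialect()] naming the cell/time/value columns.
#' @param cue_time,sampling_interval,treatment,well_id experiment metadata,
#'   see [track_table()].
#' @param on_gap `"exclude"` (default) drops gapped traces with a warning and
#'   records them in `attr(x, "gap_report")`; `"error"` aborts.
#' @return a `track_table`.
#' @export
read_track_table <- function(path, dialect = track_dialect(),
                             cue_time = NA_real_, sampling_interval = 1,
                             treatment = "untreated", well_id = "well1",
                             on_gap = c("exclude", "error")) {
  on_gap <- match.arg(on_gap)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(dialect$cell, dialect$time, dialect$value)) {
    if (!col %in% names(raw)) {
      abort(paste0("schema error: required column `", col, "` not found in ", path))
    }
  }
  df <- tibble(
    cell_id = as.character(raw[[dialect$cell]]),
    time_h = as.numeric(raw[[dialect$time]]),
    value = as.numeric(raw[[dialect$value]])
  )
  if (identical(dialect$time_unit, "frames")) df$time_h <- df$time_h * sampling_interval
  if (anyDuplicated(df[c("cell_id", "time_h")]) > 0) {
    bad <- unique(df$cell_id[duplicated(df[c("cell_id", "time_h")])])
    abort(paste0("integrity error: duplicated (cell, time) rows for cell(s): ",
                 paste(bad, collapse = ", ")))
  }
  grid <- sort(unique(df$time_h))
  gaps <- df |>
    group_by(.data$cell_id) |>
    summarise(
      n_obs = n(),
      n_expected = sum(grid >= min(.data$time_h) & grid <= max(.data$time_h)),
      .groups = "drop"
    ) |>
    filter(.data$n_obs < .data$n_expected)
  if (nrow(gaps) > 0) {
    if (on_gap == "error") {
      abort(paste0("traces with internal gaps: ", paste(gaps$cell_id, collapse = ", ")))
    }
    warn(paste0(nrow(gaps), " trace(s) with internal gaps excluded: ",
                paste(gaps$cell_id, collapse = ", ")))
    df <- filter(df, !.data$cell_id %in% gaps$cell_id)
  }
  out <- track_table(df, cue_time = cue_time, sampling_interval = sampling_interval,
                     treatment = treatment, well_id = well_id)
  attr(out, "gap_report") <- gaps
  out
}

#' Write and re-read a track table
#'
#' CSV round-trip for [track_table()] objects. Metadata attributes are stored
#' as `# key: value` comment lines ahead of the header so that
#' `read(write(x))` restores every field.
#'
#' @param x a `track_table`.
#' @param path output file path.
#' @return `write_track_table()` returns `path` invisibly;
#'   `read_track_table_rt()` returns the restored `track_table`.
#' @export
write_track_table <- function(x, path) {
  hdr <- c(
    paste0("# cue_time: ", format(cue_time(x), digits = 17)),
    paste0("# sampling_interval: ", format(sampling_interval(x), digits = 17)),
    paste0("# treatment: ", attr(x, "treatment")),
    paste0("# well_id: ", attr(x, "well_id"))
  )
  ok <- try(writeLines(hdr, path), silent = TRUE)
  if (inherits(ok, "try-error")) abort(paste0("cannot write to ", path))
  readr::write_csv(as_tibble(unclass_track(x)), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

unclass_track <- function(x) {
  class(x) <- setdiff(class(x), "track_table")
  x[c("cell_id", "time_h", "value")]
}

#' @rdname write_track_table
#' @export
read_track_table_rt <- function(path) {
  meta <- read_comment_header(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  track_table(df,
              cue_time = suppressWarnings(as.numeric(meta[["cue_time"]])),
              sampling_interval = as.numeric(meta[["sampling_interval"]]),
              treatment = meta[["treatment"]], well_id = meta[["well_id"]])
}

read_comment_header <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), ": ", fixed = TRUE)
  stats::setNames(
    lapply(kv, function(p) if (length(p) < 2) NA_character_ else paste(p[-1], collapse = ": ")),
    vapply(kv, `[[`, "", 1)
  )
}
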