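#' Write and read PTC datasets
#'
#' CSV round-trip for `ptc_dataset` tibbles (see [filter_pairs()]). Metadata
#' (treatment, dose, filtered flag and the filter thresholds) is stored as
#' `# key: value` comment lines ahead of the header; `read(write(x))`
#' restores every documented field to float round-trip precision. The eight
#' documented columns are `cell_id`, `old_phase`, `new_phase`, `shift`,
#' `tau_before`, `tau_after`, `r2_before`, `r2_after`.
#'
#' @param dataset a `ptc_dataset`.
#' @param path output CSV path.
#' @return `write_ptc_dataset()` returns `path` invisibly;
#'   `read_ptc_dataset()` the restored dataset.
#' @export
write_ptc_dataset <- function(dataset, path) {
  fs <- attr(dataset, "filter_spec") %||% list(r2_min = NA_real_, tau_bounds = c(NA_real_, NA_real_))
  hdr <- c(
    paste0("# treatment: ", attr(dataset, "treatment") %||% "untreated"),
    paste0("# dose: ", format(attr(dataset, "dose") %||% NA_real_, digits = 17)),
    paste0("# filtered: ", isTRUE(attr(dataset, "filtered"))),
    paste0("# r2_min: ", format(fs$r2_min, digits = 17)),
    paste0("# tau_bounds: ", paste(format(fs$tau_bounds, digits = 17), collapse = ","))
  )
  ok <- try(writeLines(hdr, path), silent = TRUE)
  if (inherits(ok, "try-error")) abort(paste0("cannot write to ", path))
  cols <- c("cell_id", "old_phase", "new_phase", "shift", "tau_before",
            "tau_after", "r2_before", "r2_after")
  readr::write_csv(as_tibble(dataset)[cols], path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_ptc_dataset
#' @export
read_ptc_dataset <- function(path) {
  meta <- read_comment_header(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  tb <- suppressWarnings(as.numeric(strsplit(meta[["tau_bounds"]], ",")[[1]]))
  new_ptc_dataset(df,
                  treatment = meta[["treatment"]],
                  dose = suppressWarnings(as.numeric(meta[["dose"]])),
                  filtered = identical(meta[["filtered"]], "TRUE"),
                  filter_spec = list(r2_min = suppressWarnings(as.numeric(meta[["r2_min"]])),
                                     tau_bounds = tb))
}
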