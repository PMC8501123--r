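#' Analysis configuration
#'
#' Bundles every tunable of the PTC pipeline with validated defaults:
#' * `before_window`, `after_window`: fitting windows in hours. Defaults
#'   24-96 h (pre-cue) and 120-192 h (post-cue) for a 9-day recording with
#'   the cue at 108 h; both are closed intervals sampled on the time grid.
#' * `tau_min`, `tau_max`, `tau_step`: the exhaustive period scan,
#'   20-32 h in 0.1 h increments.
#' * `r2_min`: rhythmicity threshold; a cosine fit with R^2 > 0.5 counts as
#'   rhythmic, applied in both windows.
#' * `tau_bounds`: accepted period range, 22-29 h inclusive.
#' * `detrend_window_h`: running-mean window of the z-score detrending, 48 h.
#' * `sd_mode`: z-score denominator, SD of the trend-subtracted residual
#'   (default) or of the raw track.
#' * `bootstrap_B`: bootstrap iterations, 10000.
#' * `min_pairs`: below this many filtered pairs a PTC is flagged
#'   under-powered (30).
#' * `seed`: optional integer seed for randomized operations.
#'
#' @param ... named overrides of the defaults above.
#' @return a validated named list of class `ptc_config`.
#' @examples
#' cfg <- ptc_config(after_window = c(120, 196))
#' cfg$tau_step
#' @export
ptc_config <- function(...) {
  defaults <- list(
    before_window = c(24, 96),
    after_window = c(120, 192),
    tau_min = 20, tau_max = 32, tau_step = 0.1,
    r2_min = 0.5,
    tau_bounds = c(22, 29),
    detrend_window_h = 48,
    sd_mode = "residual",
    bootstrap_B = 10000,
    min_pairs = 30,
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("all config overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("config validation error: ", msg))
  chk(is.numeric(cfg$before_window) && length(cfg$before_window) == 2 &&
        cfg$before_window[1] < cfg$before_window[2], "before_window must be an increasing pair")
  chk(is.numeric(cfg$after_window) && length(cfg$after_window) == 2 &&
        cfg$after_window[1] < cfg$after_window[2], "after_window must be an increasing pair")
  chk(cfg$tau_step > 0, "tau_step must be > 0")
  chk(cfg$tau_min > 0 && cfg$tau_min < cfg$tau_max, "need 0 < tau_min < tau_max")
  chk(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min must lie in [0, 1]")
  chk(length(cfg$tau_bounds) == 2 && cfg$tau_bounds[1] < cfg$tau_bounds[2],
      "tau_bounds must be an increasing pair")
  chk(cfg$bootstrap_B >= 1, "bootstrap_B must be >= 1")
  chk(cfg$min_pairs >= 1, "min_pairs must be >= 1")
  chk(cfg$detrend_window_h > 0, "detrend_window_h must be > 0")
  chk(cfg$sd_mode %in% c("residual", "raw"), "sd_mode must be 'residual' or 'raw'")
  if (!is.null(cfg$seed)) chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
                              "seed must be an integer")
  structure(cfg, class = "ptc_config")
}

#' Load a configuration from a YAML file
#'
#' Reads a YAML mapping of config keys (see [ptc_config()]); keys not listed
#' there are rejected, out-of-range values raise a validation error, and
#' missing keys fall back to the documented defaults. An empty file yields
#' the full default configuration.
#'
#' @param path YAML file path.
#' @return a validated `ptc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(ptc_config, lapply(raw, function(v) if (is.list(v)) unlist(v) else v))
}
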