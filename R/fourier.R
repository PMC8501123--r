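#' Two-harmonic Fourier resetting models
#'
#' A PTC is summarized by a 2-harmonic periodic model
#' `f(x) = a0 + a1*cos(2*pi*x) + b1*sin(2*pi*x) + a2*cos(4*pi*x) +
#' b2*sin(4*pi*x)` with the fundamental period fixed to one cycle of old
#' phase, fitted under one of the two canonical resetting topologies:
#'
#' * **type-1** (`fit_type1()`): the data are first transformed to PRC form
#'   (shift vs old phase) so the fitted periodic curve oscillates about a
#'   horizontal line, which forces the implied PTC
#'   `new = wrap(x + f(x))` to have mean slope exactly 1.
#' * **type-0** (`fit_type0()`): the data stay in PTC form (new phase vs old
#'   phase); the periodic fit `new = wrap(f(x))` has mean slope exactly 0.
#'   Because the y-axis is circular, new phases are first unwrapped to the
#'   real line about their circular mean (each value moved by an integer
#'   number of cycles into +/- half a cycle of the mean) so that clusters
#'   straddling the 0/1 seam fit as tight clusters, not as artefactual
#'   jumps.
#'
#' Both fits duplicate the data along the x-axis (append a copy at `x + 1`)
#' before fitting for parity with the conventional procedure; since every
#' basis function is 1-periodic this leaves the least-squares coefficients
#' unchanged (asserted numerically in the test suite). The RMSE is computed
#' on residuals wrapped into `[-0.5, 0.5)`, in new-phase units, so
#' `rmse` values of the two model kinds are directly comparable.
#'
#' @param dataset a `ptc_dataset` (needs `old_phase` and `shift` /
#'   `new_phase` columns).
#' @param min_pairs minimal number of pairs required (default 10).
#' @return an object of class `resetting_model`: list with `kind`,
#'   `coefficients` (a0, a1, b1, a2, b2), `rmse`, `n_pairs`.
#' @examples
#' ds <- simulate_phase_pairs(200, response_map("type1", A = 0.1), seed = 1)
#' m <- fit_type1(ds)
#' glance(m)
#' @export
fit_type1 <- function(dataset, min_pairs = 10) {
  check_fit_input(dataset, min_pairs)
  x <- wrap_phase(dataset$old_phase)
  d <- dataset$shift
  cf <- fourier_ls(c(x, x + 1), c(d, d))
  f <- fourier_eval(cf, x)
  new_resetting_model("type1", cf,
                      rmse = sqrt(mean(wrap_shift(d - f)^2)),
                      n_pairs = length(x))
}

#' @rdname fit_type1
#' @export
fit_type0 <- function(dataset, min_pairs = 10) {
  check_fit_input(dataset, min_pairs)
  x <- wrap_phase(dataset$old_phase)
  y <- unwrap_about_mean(dataset$new_phase)
  cf <- fourier_ls(c(x, x + 1), c(y, y))
  f <- fourier_eval(cf, x)
  new_resetting_model("type0", cf,
                      rmse = sqrt(mean(wrap_shift(y - f)^2)),
                      n_pairs = length(x))
}

check_fit_input <- function(dataset, min_pairs) {
  if (nrow(dataset) < min_pairs) {
    abort(sprintf("dataset too small: %d pairs (< %d)", nrow(dataset), min_pairs))
  }
  invisible(dataset)
}

# shift each phase by an integer so it lies within +/- 0.5 of the circular mean
unwrap_about_mean <- function(phases) {
  mu <- circular_mean(wrap_phase(phases))
  mu + wrap_shift(phases - mu)
}

fourier_basis <- function(x) {
  cbind(1, cos(2 * pi * x), sin(2 * pi * x), cos(4 * pi * x), sin(4 * pi * x))
}

fourier_ls <- function(x, y) {
  cf <- .lm.fit(fourier_basis(x), y)$coefficients
  names(cf) <- c("a0", "a1", "b1", "a2", "b2")
  cf
}

fourier_eval <- function(cf, x) drop(fourier_basis(x) %*% cf)

new_resetting_model <- function(kind, cf, rmse, n_pairs) {
  structure(list(kind = kind, coefficients = cf, rmse = rmse, n_pairs = n_pairs),
            class = "resetting_model")
}

#' @export
print.resetting_model <- function(x, ...) {
  cat(sprintf("<resetting_model> %s | rmse %.4f | n %d\n", x$kind, x$rmse, x$n_pairs))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predictions from a resetting model
#'
#' @param object a `resetting_model`.
#' @param x old phases (cycle units); defaults to a dense grid.
#' @param type `"new_phase"` for the predicted new phase in `[0,1)`,
#'   `"shift"` for the implied shift `wrap(new - old)` in `[-0.5, 0.5)`,
#'   `"curve"` for the raw periodic model value `f(x)`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.resetting_model <- function(object, x = seq(0, 0.999, by = 0.001),
                                    type = c("new_phase", "shift", "curve"), ...) {
  type <- match.arg(type)
  f <- fourier_eval(object$coefficients, x)
  switch(type,
    curve = f,
    new_phase = if (object$kind == "type1") wrap_phase(x + f) else wrap_phase(f),
    shift = if (object$kind == "type1") wrap_shift(f) else wrap_shift(f - x)
  )
}

#' @exportS3Method generics::tidy
tidy.resetting_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.resetting_model <- function(x, ...) {
  ms <- max_shift(x)
  out <- tibble(kind = x$kind, rmse = x$rmse, n_pairs = x$n_pairs,
                max_advance = ms$max_advance, max_delay = ms$max_delay,
                max_abs_shift = ms$max_abs, phase_of_max = ms$phase_of_max)
  if (x$kind == "type0") {
    fp <- final_phase_stats(x)
    out$mean_final_phase <- fp$mean_final_phase
    out$final_phase_range <- fp$final_phase_range
  }
  out
}

#' Extremal phase shifts implied by a resetting model
#'
#' Evaluates the implied shift curve `wrap(predicted_new(x) - x)` on a dense
#' grid over `[0, 1)` and reports the maximal advance (largest positive
#' shift), maximal delay (most negative), maximal absolute shift, and the
#' old phase at which the absolute shift peaks. For a saturating type-0
#' response the maximal absolute shift reaches the wrap bound of 0.5
#' (half a cycle, i.e. +/- 12 h on a 24 h clock).
#'
#' @param model a `resetting_model`.
#' @param grid_step grid resolution in cycle units.
#' @return a tibble with `max_advance`, `max_delay`, `max_abs`,
#'   `phase_of_max`.
#' @export
max_shift <- function(model, grid_step = 0.001) {
  x <- seq(0, 1 - grid_step, by = grid_step)
  s <- predict(model, x, type = "shift")
  tibble(
    max_advance = max(c(s[s > 0], 0)),
    max_delay = min(c(s[s < 0], 0)),
    max_abs = max(abs(s)),
    phase_of_max = x[which.max(abs(s))]
  )
}

#' Final-phase summary of a type-0 model
#'
#' For a strong (type-0) response the model's value `f(x)` *is* the final
#' phase; this returns its circular mean and its range (max - min of the
#' unwrapped model curve) over a dense grid.
#'
#' @param model a `resetting_model` of kind `"type0"`.
#' @param grid_step grid resolution.
#' @return tibble with `mean_final_phase` (in `[0,1)`) and
#'   `final_phase_range` (cycle units).
#' @export
final_phase_stats <- function(model, grid_step = 0.001) {
  if (!identical(model$kind, "type0")) {
    abort("final_phase_stats() is defined for type-0 models only")
  }
  x <- seq(0, 1 - grid_step, by = grid_step)
  f <- fourier_eval(model$coefficients, x)
  tibble(mean_final_phase = circular_mean(wrap_phase(f)),
         final_phase_range = max(f) - min(f))
}

#' Well-equivalence of a single mixed-phase culture
#'
#' A single non-synchronized well read out at a given phase resolution
#' covers the whole cycle at once: it is equivalent to running
#' `cycle_h / resolution_h` conventional single-treatment-time cultures
#' (24 wells for a 24 h cycle probed at 1 h resolution), excluding
#' biological replicates.
#'
#' @param cycle_h cycle length in hours.
#' @param resolution_h phase resolution in hours.
#' @return number of equivalent conventional cultures.
#' @export
well_equivalents <- function(cycle_h = 24, resolution_h = 1) {
  if (cycle_h <= 0 || resolution_h <= 0) abort("arguments must be positive")
  cycle_h / resolution_h
}
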