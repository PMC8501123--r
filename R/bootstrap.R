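#' Bootstrap tests on PTC datasets
#'
#' Three resampling tests characterize a PTC, all i.i.d. with replacement at
#' the cell level and seeded for reproducibility. p-values use add-one
#' smoothing, `p = (1 + #exceedances) / (B + 1)`, so they are never exactly
#' zero.
#'
#' `bootstrap_response_test()` asks whether a treated PTC shows any phase
#' response: the null distribution is the maximal absolute shift of type-1
#' fits to `B` control resamples of the test group's size; the observed
#' statistic is the test group's own type-1 maximal absolute shift, and the
#' one-sided p-value is the fraction of null values at least as large.
#'
#' @param test,control `ptc_dataset`s (test = treated, control = untreated).
#' @param B bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param min_control minimal control size.
#' @return a `ptc_boot` object (list): `test`, `B`, `observed`, `p_value`,
#'   `ci_95`, `significant`, `seed`; see also [tidy.ptc_boot()].
#' @export
bootstrap_response_test <- function(test, control, B = 10000, seed = 1L,
                                    min_control = 20) {
  if (B < 1) abort("B must be >= 1")
  if (nrow(control) < min_control) {
    abort(sprintf("control too small: %d pairs (< %d)", nrow(control), min_control))
  }
  set.seed(seed)
  obs <- max_shift(fit_type1(test))$max_abs
  n_test <- nrow(test)
  xc <- wrap_phase(control$old_phase)
  dc <- control$shift
  null <- vapply(seq_len(B), function(b) {
    idx <- sample.int(length(xc), n_test, replace = TRUE)
    max_abs_shift_type1(xc[idx], dc[idx])
  }, 0)
  p <- (1 + sum(null >= obs)) / (B + 1)
  new_ptc_boot("response", B, observed = obs, p_value = p,
               ci_95 = unname(quantile(null, c(0.025, 0.975))),
               significant = p < 0.05, seed = seed)
}

# fast inner loop: type-1 max abs shift without object construction.
# x-duplication is skipped because the 1-periodic basis makes it a no-op
# on the coefficients (property asserted in the test suite).
max_abs_shift_type1 <- function(x, d, grid = fourier_basis(seq(0, 0.999, by = 0.001))) {
  cf <- .lm.fit(fourier_basis(x), d)$coefficients
  max(abs(wrap_shift(drop(grid %*% cf))))
}

#' @describeIn bootstrap_response_test Selection between type-1 and type-0.
#' The dataset is resampled `B` times; both models are fitted per iteration
#' and `D = RMSE_type0 - RMSE_type1` collected. The type-0 model is accepted
#' (null of type-1 rejected) when `D < 0` in over 95 % of resamples, i.e.
#' `p_type0 = P(D > 0) < 0.05` (one-sided, add-one smoothed). Degenerate
#' resamples (no dispersion in old phase) are redrawn up to a cap.
#' @param dataset the tested `ptc_dataset`.
#' @export
bootstrap_model_selection <- function(dataset, B = 10000, seed = 1L) {
  if (B < 1) abort("B must be >= 1")
  set.seed(seed)
  obs_d <- fit_type0(dataset)$rmse - fit_type1(dataset)$rmse
  x <- wrap_phase(dataset$old_phase)
  d <- dataset$shift
  y <- dataset$new_phase
  n <- length(x)
  redraws <- 0
  D <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0
    while (sd(x[idx]) < 1e-9 && tries < 10) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- tries + 1
      redraws <<- redraws + 1
    }
    rmse_pair_diff(x[idx], d[idx], y[idx])
  }, 0)
  p0 <- (1 + sum(D > 0)) / (B + 1)
  out <- new_ptc_boot("model_selection", B, observed = obs_d, p_value = p0,
                      ci_95 = unname(quantile(D, c(0.025, 0.975))),
                      significant = p0 < 0.05, seed = seed)
  out$selected <- if (p0 < 0.05) "type0" else "type1"
  out$n_redraws <- redraws
  out
}

# rmse(type0) - rmse(type1) on one resample
rmse_pair_diff <- function(x, d, y) {
  cf1 <- .lm.fit(fourier_basis(x), d)$coefficients
  r1 <- sqrt(mean(wrap_shift(d - drop(fourier_basis(x) %*% cf1))^2))
  yu <- unwrap_about_mean(y)
  cf0 <- .lm.fit(fourier_basis(x), yu)$coefficients
  r0 <- sqrt(mean(wrap_shift(yu - drop(fourier_basis(x) %*% cf0))^2))
  r0 - r1
}

#' @describeIn bootstrap_response_test Two-sided group difference in a PTC
#' summary metric. `B` paired resamples of the two groups (each at its own
#' size) give a percentile 95 % CI of `metric(A*) - metric(B*)`; the null of
#' no difference is rejected when 0 falls outside the CI.
#' @param groupA,groupB `ptc_dataset`s.
#' @param metric one of `"max_abs_shift"`, `"max_advance"`, `"max_delay"`,
#'   `"mean_final_phase"`.
#' @export
bootstrap_group_difference <- function(groupA, groupB,
                                       metric = c("max_abs_shift", "max_advance",
                                                  "max_delay", "mean_final_phase"),
                                       B = 10000, seed = 1L) {
  if (B < 1) abort("B must be >= 1")
  metric <- match.arg(metric)
  set.seed(seed)
  mfun <- metric_fun(metric)
  obs <- mfun(groupA) - mfun(groupB)
  nA <- nrow(groupA); nB <- nrow(groupB)
  diffs <- vapply(seq_len(B), function(b) {
    a <- groupA[sample.int(nA, nA, replace = TRUE), , drop = FALSE]
    bb <- groupB[sample.int(nB, nB, replace = TRUE), , drop = FALSE]
    mfun(a) - mfun(bb)
  }, 0)
  ci <- unname(quantile(diffs, c(0.025, 0.975)))
  frac_above <- (1 + sum(diffs > 0)) / (B + 1)
  p <- 2 * min(frac_above, 1 - frac_above + 1 / (B + 1))
  new_ptc_boot("group_difference", B, observed = obs, p_value = min(p, 1),
               ci_95 = ci, significant = ci[1] > 0 || ci[2] < 0, seed = seed)
}

metric_fun <- function(metric) {
  switch(metric,
    max_abs_shift = function(ds) max_shift(fit_type1(ds))$max_abs,
    max_advance = function(ds) max_shift(fit_type1(ds))$max_advance,
    max_delay = function(ds) max_shift(fit_type1(ds))$max_delay,
    mean_final_phase = function(ds) final_phase_stats(fit_type0(ds))$mean_final_phase,
    abort(paste0("unknown metric: ", metric))
  )
}

new_ptc_boot <- function(test, B, observed, p_value, ci_95, significant, seed) {
  structure(list(test = test, B = B, observed = observed, p_value = p_value,
                 ci_95 = ci_95, significant = significant, seed = seed),
            class = "ptc_boot")
}

#' @export
print.ptc_boot <- function(x, ...) {
  cat(sprintf("<ptc_boot:%s> B=%d | observed %.4f | p %.4g | CI95 [%.4f, %.4f]%s\n",
              x$test, x$B, x$observed, x$p_value, x$ci_95[1], x$ci_95[2],
              if (!is.null(x$selected)) paste0(" | selected ", x$selected) else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ptc_boot <- function(x, ...) {
  tibble(test = x$test, observed = x$observed, p.value = x$p_value,
         conf.low = x$ci_95[1], conf.high = x$ci_95[2],
         significant = x$significant, B = x$B, seed = x$seed,
         selected = x$selected %||% NA_character_)
}

#' Period-change t-test between groups
#'
#' Per cell, the period change is `tau_after - tau_before`; groups are
#' compared by a pooled-variance two-sided two-sample Student's t-test.
#'
#' @param groupA,groupB phase-pair tibbles with `tau_before`, `tau_after`
#'   (>= 3 cells each).
#' @return broom-style tibble: `estimate` (mean difference A - B),
#'   `statistic`, `p.value`, `parameter` (df), `conf.low`, `conf.high`.
#' @export
period_change_test <- function(groupA, groupB) {
  if (nrow(groupA) < 3 || nrow(groupB) < 3) abort("each group needs >= 3 cells")
  dA <- groupA$tau_after - groupA$tau_before
  dB <- groupB$tau_after - groupB$tau_before
  tt <- t.test(dA, dB, var.equal = TRUE)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         statistic = unname(tt$statistic), p.value = tt$p.value,
         parameter = unname(tt$parameter),
         conf.low = tt$conf.int[1], conf.high = tt$conf.int[2])
}

#' Sequential response classification
#'
#' The decision logic for one treated PTC against an untreated control:
#' first the response test; if no significant response, the verdict is
#' `"no-response"`. Otherwise the model-selection bootstrap decides between
#' `"type-1"` and `"type-0"`.
#'
#' @param test,control `ptc_dataset`s.
#' @param B bootstrap iterations.
#' @param seed integer seed.
#' @return a list with `decision`, `response` (ptc_boot), `selection`
#'   (ptc_boot or NULL), and `metrics` (glance of the selected model).
#' @export
classify_response <- function(test, control, B = 10000, seed = 1L) {
  resp <- bootstrap_response_test(test, control, B = B, seed = seed)
  if (!resp$significant) {
    return(list(decision = "no-response", response = resp, selection = NULL,
                metrics = glance(fit_type1(test))))
  }
  sel <- bootstrap_model_selection(test, B = B, seed = seed + 1L)
  model <- if (sel$selected == "type0") fit_type0(test) else fit_type1(test)
  list(decision = if (sel$selected == "type0") "type-0" else "type-1",
       response = resp, selection = sel, metrics = glance(model))
}
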