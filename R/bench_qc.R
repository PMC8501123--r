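#' Dense-grid cosine fit oracle
#'
#' Independent re-implementation of the windowed cosine fit on a 10x denser
#' period grid, written naively (full `lm()` per candidate period). Used to
#' bound the grid error of [fit_cosine_scan()] and to localize off-grid
#' periods; deliberately shares no code with the main fitter.
#'
#' @param tracks traces tibble (`cell_id`, `time_h`, `value`).
#' @param window numeric length-2 window, hours.
#' @param tau_min,tau_max scan range, hours.
#' @param dense_step period grid step, hours (default 0.01).
#' @return a tibble like [fit_cosine_scan()]'s.
#' @export
brute_force_fit_oracle <- function(tracks, window, tau_min = 20, tau_max = 32,
                                   dense_step = 0.01) {
  rows <- lapply(split(as_tibble(tracks), tracks$cell_id), function(tr) {
    sel <- tr$time_h >= window[1] & tr$time_h <= window[2]
    tw <- tr$time_h[sel]; yw <- tr$value[sel]
    best_r2 <- -Inf; best <- NULL
    for (tau in seq(tau_min, tau_max, by = dense_step)) {
      m <- stats::lm(yw ~ cos(2 * pi * tw / tau) + sin(2 * pi * tw / tau))
      r2 <- summary(m)$r.squared
      if (r2 > best_r2) {
        best_r2 <- r2
        cf <- coef(m)
        best <- list(tau = tau, mesor = cf[1], a = cf[2], b = cf[3])
      }
    }
    phi <- atan2(best$b, best$a)
    t0 <- phi / (2 * pi) * best$tau
    peak <- window[1] + ((t0 - window[1]) %% best$tau)
    tibble(cell_id = tr$cell_id[1], period = best$tau, peak_time = peak,
           amplitude = sqrt(best$a^2 + best$b^2), mesor = unname(best$mesor),
           r2 = best_r2, window_start = window[1], window_end = window[2])
  })
  list_rbind(rows)
}

#' Statistical calibration suite
#'
#' Seeded Monte-Carlo harness that measures, at reduced bootstrap depth, the
#' operating characteristics the package's statistics are supposed to have:
#' type-I error of the response test on null data, classification power on
#' strong type-0 and weak type-1 maps, and parameter recovery of the type-1
#' model. Pass bounds are exact binomial limits at the stated repeat counts.
#'
#' The type-I-error block draws each null test well fresh and compares it
#' against one large pooled control (`n_control` pairs, default 2000). The
#' control must be much larger than the test wells for the bootstrap null to
#' approximate the sampling distribution of the max-shift statistic: with a
#' control of similar size to the test group, resampling adds the control's
#' own estimation noise on top of the sampling noise and the test becomes
#' conservative (a property of the resampling scheme worth knowing when
#' interpreting borderline p-values on small controls).
#'
#' @param n_null,n_power Monte-Carlo repeats for the calibration and power
#'   blocks.
#' @param n_pairs pairs per simulated well.
#' @param n_control pairs in the pooled null control.
#' @param B bootstrap iterations per test.
#' @param seed integer seed.
#' @return a tibble with one row per check: `check`, `value`, `bound_lo`,
#'   `bound_hi`, `pass`.
#' @export
calibration_suite <- function(n_null = 200, n_power = 100, n_pairs = 150,
                              n_control = 2000, B = 1000, seed = 1L) {
  set.seed(seed)
  null_map <- response_map("none", phase_noise_sd = 0.05)
  control <- simulate_phase_pairs(n_control, null_map, seed = seed)

  rej <- vapply(seq_len(n_null), function(i) {
    test <- simulate_phase_pairs(n_pairs, null_map, seed = seed + i)
    bootstrap_response_test(test, control, B = B, seed = seed + 10000 + i)$significant
  }, TRUE)
  alpha_bounds <- stats::qbinom(c(0.005, 0.995), n_null, 0.05) / n_null
  type1_err <- mean(rej)

  sel0 <- vapply(seq_len(n_power), function(i) {
    ds <- simulate_phase_pairs(n_pairs,
                               response_map("type0", target = 0.3, B = 0.05,
                                            phase_noise_sd = 0.05),
                               seed = seed + 20000 + i)
    bootstrap_model_selection(ds, B = B, seed = seed + 30000 + i)$selected == "type0"
  }, TRUE)

  keep1 <- vapply(seq_len(n_power), function(i) {
    ds <- simulate_phase_pairs(n_pairs,
                               response_map("type1", A = 0.08, psi = 0.6,
                                            phase_noise_sd = 0.05),
                               seed = seed + 40000 + i)
    bootstrap_model_selection(ds, B = B, seed = seed + 50000 + i)$selected == "type1"
  }, TRUE)

  rec <- simulate_phase_pairs(400,
                              response_map("type1", A = 0.15, psi = 0.6,
                                           phase_noise_sd = 0.02),
                              seed = seed + 60000)
  ms <- max_shift(fit_type1(rec))
  adv_err <- abs(ms$max_advance - 0.15)

  tibble(
    check = c("response_type_I_error", "type0_power", "type1_retention",
              "max_shift_recovery_error"),
    value = c(type1_err, mean(sel0), mean(keep1), adv_err),
    bound_lo = c(alpha_bounds[1], 0.95, 0.95, 0),
    bound_hi = c(alpha_bounds[2], 1, 1, 0.02),
    pass = c(type1_err >= alpha_bounds[1] & type1_err <= alpha_bounds[2],
             mean(sel0) >= 0.95, mean(keep1) >= 0.95, adv_err <= 0.02)
  )
}
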