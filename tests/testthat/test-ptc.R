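test_that("TIPA arithmetic matches the hand-worked example", {
  res <- tipa_old_phase(90, 26, 24, 108)
  expect_equal(res$old_phase, 18 / 26)
  expect_equal(res$expected_peak_time, 108 + (1 - 18 / 26) * 24)
  # cue at a before-fit peak with equal periods
  res2 <- tipa_old_phase(82, 26, 26, 82 + 26)
  expect_equal(res2$old_phase, 0)
  expect_equal(res2$expected_peak_time, 108 + 26)
  # TIPA is period-aware: same peak/cue, different tau_before
  expect_false(tipa_old_phase(90, 24, 24, 108)$old_phase ==
                 tipa_old_phase(90, 26, 24, 108)$old_phase)
  expect_error(tipa_old_phase(90, -26, 24, 108), "positive")
})

test_that("new-phase projection and the advance sign convention", {
  # after peak exactly at the null curve's expected peak: zero shift
  exp_peak <- tipa_old_phase(90, 26, 24, 108)$expected_peak_time
  new <- new_phase_from_after_fit(exp_peak, 24, 108)
  expect_equal(new, 18 / 26, tolerance = 1e-12)
  # peak 6 h earlier than expected at tau 24 -> advance of +0.25
  new_adv <- new_phase_from_after_fit(exp_peak - 6, 24, 108)
  expect_equal(wrap_shift(new_adv - 18 / 26), 0.25)
  # half-period displacement sits at the wrap boundary: exactly +0.5 maps
  # to -0.5 (half-open convention) and the emitted value stays in range
  expect_identical(wrap_shift(0.5), -0.5)
  new_half <- new_phase_from_after_fit(exp_peak - 12, 24, 108)
  sh <- wrap_shift(new_half - 18 / 26)
  expect_equal(abs(sh), 0.5, tolerance = 1e-9)
  expect_true(sh >= -0.5 && sh < 0.5)
})

test_that("phase pairs reduce to naive differencing when periods agree", {
  before <- tibble::tibble(cell_id = "c1", period = 25, peak_time = 88,
                           amplitude = 1, mesor = 0, r2 = 0.9,
                           window_start = 24, window_end = 96)
  after <- dplyr::mutate(before, peak_time = 117, window_start = 120,
                         window_end = 192)
  pp <- make_phase_pairs(before, after, 108)
  naive <- wrap_shift(wrap_phase((108 - 117) / 25) - wrap_phase((108 - 88) / 25))
  expect_equal(pp$shift, naive)
  # identical dynamics in both windows: zero shift
  same <- make_phase_pairs(before, dplyr::mutate(before, peak_time = 88 + 25),
                           108)
  expect_equal(same$shift, 0)
})

test_that("phases and shifts close under wrapping for arbitrary fits", {
  set.seed(33)
  for (i in 1:50) {
    tb <- runif(1, 20, 32); ta <- runif(1, 20, 32)
    peak_b <- runif(1, 24, 96); peak_a <- runif(1, 120, 192)
    before <- tibble::tibble(cell_id = "x", period = tb, peak_time = peak_b,
                             amplitude = 1, mesor = 0, r2 = 1,
                             window_start = 24, window_end = 96)
    after <- tibble::tibble(cell_id = "x", period = ta, peak_time = peak_a,
                            amplitude = 1, mesor = 0, r2 = 1,
                            window_start = 120, window_end = 192)
    pp <- make_phase_pairs(before, after, 108)
    expect_true(pp$old_phase >= 0 && pp$old_phase < 1)
    expect_true(pp$new_phase >= 0 && pp$new_phase < 1)
    expect_true(pp$shift >= -0.5 && pp$shift < 0.5)
    expect_equal(pp$shift, wrap_shift(pp$new_phase - pp$old_phase))
  }
})

test_that("the pair filter applies both windows and inclusive period bounds", {
  mk <- function(r2b, r2a, tb, ta) {
    tibble::tibble(cell_id = paste0("c", seq_along(r2b)), old_phase = 0.5,
                   new_phase = 0.5, shift = 0, tau_before = tb, tau_after = ta,
                   r2_before = r2b, r2_after = r2a)
  }
  pairs <- mk(c(0.9, 0.9, 0.9, 0.4, 0.9), c(0.8, 0.8, 0.8, 0.9, 0.4),
              c(26, 22, 26, 26, 26), c(25, 29, 29.5, 25, 25))
  ds <- filter_pairs(pairs)
  # kept: both R2 > 0.5 and both periods in [22, 29] inclusive
  expect_equal(ds$cell_id, c("c1", "c2"))
  rep_tbl <- attr(ds, "filter_report")
  expect_equal(rep_tbl$n_input, 5)
  expect_equal(rep_tbl$n_kept, 2)
  expect_equal(rep_tbl$n_fail_r2, 2)
  expect_equal(rep_tbl$n_fail_tau, 1)
  empty <- filter_pairs(pairs[0, ])
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "ptc_dataset")
})

test_that("an unperturbed population reconstructs the diagonal PTC", {
  sim <- simulate_population(sim_config(
    n_cells = 400, response = response_map("none", phase_noise_sd = 0.02),
    seed = 19
  ))
  ds <- assemble_ptc(sim$tracks)
  expect_gt(nrow(ds), 300)
  expect_lt(circ_dist(circular_mean(wrap_phase(ds$shift)), 0), 0.02)
  expect_lt(sqrt(mean(ds$shift^2)), 0.05)
  fr <- funnel_report(ds)
  expect_equal(fr$stage[1], "tracked")
  expect_true(all(diff(fr$n) <= 0))
})

test_that("a strong resetting population collapses onto the target phase", {
  sim <- simulate_population(sim_config(
    n_cells = 200,
    response = response_map("type0", target = 0.3, B = 0.05,
                            phase_noise_sd = 0.02),
    seed = 23
  ))
  ds <- assemble_ptc(sim$tracks)
  expect_lt(circ_dist(circular_mean(ds$new_phase), 0.3), 0.03)
  expect_lt(circular_sd(ds$new_phase), 0.08)
  # the bulk of cells lands within the attractor's modulation band
  expect_lt(unname(quantile(circ_dist(ds$new_phase, 0.3), 0.95)), 0.1)
})

test_that("the assembled PTC is invariant to affine intensity transforms", {
  sim <- simulate_population(sim_config(n_cells = 60, seed = 29))
  ds1 <- assemble_ptc(sim$tracks)
  doubled <- sim$tracks
  doubled$value <- 2 * doubled$value + 11
  ds2 <- assemble_ptc(doubled)
  expect_equal(ds1$old_phase, ds2$old_phase, tolerance = 1e-9)
  expect_equal(ds1$new_phase, ds2$new_phase, tolerance = 1e-9)
})

test_that("end-to-end recovery of a weak resetting map", {
  sim <- simulate_population(sim_config(
    n_cells = 400,
    response = response_map("type1", A = 0.15, psi = 0.6,
                            phase_noise_sd = 0.02),
    seed = 11
  ))
  ds <- assemble_ptc(sim$tracks)
  true_shift <- 0.15 * sin(2 * pi * (ds$old_phase - 0.6))
  expect_lt(sqrt(mean(wrap_shift(ds$shift - true_shift)^2)), 0.04)
})

test_that("under-powered assemblies warn", {
  sim <- simulate_population(sim_config(n_cells = 10, seed = 31))
  expect_warning(assemble_ptc(sim$tracks), "under-powered")
})

test_that("phase-plane binning averages circularly in 0.05 bins", {
  old <- seq(0.025, 0.975, by = 0.05) # one point per bin center
  ident <- pairs_dataset(old, old)
  b <- bin_phase_plane(ident, doses = 1)
  expect_equal(nrow(b), 20)
  expect_equal(b$new_phase_mean, b$old_bin, tolerance = 1e-9)
  # type-0 dataset: constant row at the target
  const <- pairs_dataset(old, rep(0.3, 20))
  b0 <- bin_phase_plane(list(ident, const), doses = c(1, 2))
  expect_equal(unique(b0$new_phase_mean[b0$dose == 2]), 0.3, tolerance = 1e-9)
  # empty bins are NA
  sparse <- pairs_dataset(c(0.01, 0.02), c(0.5, 0.5))
  bs <- bin_phase_plane(sparse, doses = 1)
  expect_true(is.na(bs$new_phase_mean[bs$old_bin == 0.525]))
  expect_equal(sum(!is.na(bs$new_phase_mean)), 1)
})

test_that("double plotting duplicates points one cycle over", {
  ds <- pairs_dataset(c(0.2, 0.8), c(0.4, 0.1))
  dp <- double_plot(ds, "ptc")
  expect_equal(nrow(dp), 4)
  expect_equal(dp$old_phase[3:4], ds$old_phase + 1)
  expect_equal(dp$y[3:4], ds$new_phase + 1)
  dprc <- double_plot(ds, "prc")
  expect_equal(dprc$y[3:4], ds$shift)
  expect_equal(nrow(double_plot(pairs_dataset(numeric(), numeric()))), 0)
})
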