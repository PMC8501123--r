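test_that("the type-1 model recovers exact basis members", {
  x <- seq(0, 0.99, by = 0.01)
  ds <- pairs_dataset(x, x + 0.1 * sin(2 * pi * x))
  m <- fit_type1(ds)
  cf <- m$coefficients
  expect_equal(cf["b1"], c(b1 = 0.1), tolerance = 1e-10)
  expect_lt(max(abs(cf[c("a0", "a1", "a2", "b2")])), 1e-10)
  expect_lt(m$rmse, 1e-10)
  # null data: flat model
  null <- pairs_dataset(x, x)
  expect_lt(max(abs(predict(fit_type1(null), type = "curve"))), 1e-10)
  expect_error(fit_type1(pairs_dataset(runif(5), runif(5))), "too small")
})

test_that("x-duplication leaves the fitted coefficients unchanged", {
  set.seed(44)
  for (i in 1:10) {
    x <- runif(60)
    y <- runif(60)
    X1 <- cbind(1, cos(2 * pi * x), sin(2 * pi * x), cos(4 * pi * x), sin(4 * pi * x))
    xd <- c(x, x + 1)
    X2 <- cbind(1, cos(2 * pi * xd), sin(2 * pi * xd), cos(4 * pi * xd), sin(4 * pi * xd))
    c1 <- .lm.fit(X1, y)$coefficients
    c2 <- .lm.fit(X2, c(y, y))$coefficients
    expect_lt(max(abs(c1 - c2)), 1e-10)
  }
})

test_that("the type-0 model handles the circular seam by unwrapping", {
  x <- seq(0, 0.99, by = 0.01)
  # constant final phase: exact fit
  m <- fit_type0(pairs_dataset(x, rep(0.3, length(x))))
  expect_equal(predict(m, c(0.1, 0.6), "new_phase"), c(0.3, 0.3),
               tolerance = 1e-10)
  expect_lt(m$rmse, 1e-12)

  # final phases straddling the 0/1 seam: rmse reflects the noise, not ~0.5
  set.seed(5)
  noise <- rnorm(length(x), 0, 0.03)
  m2 <- fit_type0(pairs_dataset(x, wrap_phase(0.98 + noise)))
  expect_lt(m2$rmse, 0.05)
  expect_lt(circ_dist(final_phase_stats(m2)$mean_final_phase, 0.98), 0.02)

  # perfect type-1 data is fitted worse by the type-0 topology
  d1 <- pairs_dataset(x, x + 0.12 * sin(2 * pi * (x - 0.6)))
  expect_gt(fit_type0(d1)$rmse, fit_type1(d1)$rmse)
})

test_that("extremal shifts and final-phase stats follow closed forms", {
  x <- seq(0, 0.99, by = 0.01)
  m <- fit_type1(pairs_dataset(x, x + 0.1 * sin(2 * pi * x)))
  ms <- max_shift(m)
  expect_equal(ms$max_advance, 0.1, tolerance = 1e-6)
  expect_equal(ms$max_delay, -0.1, tolerance = 1e-6)
  expect_true(circ_dist(ms$phase_of_max, 0.25) < 2e-3 ||
                circ_dist(ms$phase_of_max, 0.75) < 2e-3)

  # zero model
  m0 <- fit_type1(pairs_dataset(x, x))
  expect_equal(max_shift(m0)$max_abs, 0, tolerance = 1e-9)

  mt <- fit_type0(pairs_dataset(x, wrap_phase(0.3 + 0.05 * sin(2 * pi * x))))
  fp <- final_phase_stats(mt)
  expect_equal(fp$mean_final_phase, 0.3, tolerance = 1e-6)
  expect_equal(fp$final_phase_range, 0.1, tolerance = 1e-6)
  expect_error(final_phase_stats(m), "type-0")
})

test_that("a saturating type-0 response reaches the half-cycle wrap bound", {
  x <- seq(0.0025, 0.9975, by = 0.005)
  m0 <- fit_type0(pairs_dataset(x, rep(0.3, length(x))))
  expect_equal(max_shift(m0)$max_abs, 0.5)
  # and no model can exceed it
  set.seed(6)
  for (i in 1:20) {
    ds <- pairs_dataset(runif(40), runif(40))
    expect_lte(max_shift(fit_type1(ds))$max_abs, 0.5)
    expect_lte(max_shift(fit_type0(ds))$max_abs, 0.5)
  }
})

test_that("the response test rejects real resetting and respects its guards", {
  null_map <- response_map("none", phase_noise_sd = 0.05)
  control <- simulate_phase_pairs(2000, null_map, seed = 1)
  strong <- simulate_phase_pairs(150, response_map("type1", A = 0.15, psi = 0.6,
                                                   phase_noise_sd = 0.05),
                                 seed = 2)
  bt <- bootstrap_response_test(strong, control, B = 500, seed = 3)
  expect_lt(bt$p_value, 0.01)
  expect_true(bt$significant)
  expect_gt(bt$p_value, 0) # add-one smoothing
  expect_error(bootstrap_response_test(strong, control[1:5, ], B = 10),
               "control too small")
  expect_error(bootstrap_response_test(strong, control, B = 0), "B must be")
})

test_that("model selection distinguishes strong from weak resetting", {
  d0 <- simulate_phase_pairs(150, response_map("type0", target = 0.3, B = 0.05,
                                               phase_noise_sd = 0.05),
                             seed = 7)
  s0 <- bootstrap_model_selection(d0, B = 500, seed = 8)
  expect_equal(s0$selected, "type0")
  expect_lt(s0$p_value, 0.01)
  expect_lt(s0$observed, 0) # RMSE0 < RMSE1 on type-0 data

  d1 <- simulate_phase_pairs(150, response_map("type1", A = 0.08, psi = 0.6,
                                               phase_noise_sd = 0.05),
                             seed = 9)
  s1 <- bootstrap_model_selection(d1, B = 500, seed = 10)
  expect_equal(s1$selected, "type1")
  expect_gte(s1$p_value, 0.05)
})

test_that("group differences are detected and absent where they should be", {
  mapA <- response_map("type1", A = 0.15, psi = 0.6, phase_noise_sd = 0.05)
  mapB <- response_map("type1", A = 0.05, psi = 0.6, phase_noise_sd = 0.05)
  a <- simulate_phase_pairs(150, mapA, seed = 11)
  b <- simulate_phase_pairs(150, mapB, seed = 12)
  gd <- bootstrap_group_difference(a, b, "max_abs_shift", B = 400, seed = 13)
  expect_true(gd$significant)
  expect_gt(gd$ci_95[1], 0)

  a2 <- simulate_phase_pairs(150, mapA, seed = 14)
  gd2 <- bootstrap_group_difference(a, a2, "max_abs_shift", B = 400, seed = 15)
  expect_false(gd2$significant)
  expect_error(bootstrap_group_difference(a, b, "not_a_metric", B = 10))
  expect_error(bootstrap_group_difference(a, b, B = 0), "B must be")
})

test_that("the period-change t-test matches textbook arithmetic", {
  gA <- tibble::tibble(tau_before = c(26, 25, 27), tau_after = c(25, 24, 25.5))
  gB <- tibble::tibble(tau_before = c(26, 25.5, 26.5), tau_after = c(26, 25.6, 26.2))
  res <- period_change_test(gA, gB)
  dA <- gA$tau_after - gA$tau_before
  dB <- gB$tau_after - gB$tau_before
  sp2 <- (2 * var(dA) + 2 * var(dB)) / 4
  tman <- (mean(dA) - mean(dB)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, tman)
  expect_equal(res$parameter, 4)

  # identical groups: t = 0, p = 1
  same <- period_change_test(gA, gA)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(period_change_test(gA[1:2, ], gB), ">= 3")

  # simulated 1 h shortening is detected
  set.seed(16)
  big <- tibble::tibble(tau_before = rnorm(100, 26, 1),
                        tau_after = rnorm(100, 25, 1))
  ctrl <- tibble::tibble(tau_before = rnorm(100, 26, 1),
                         tau_after = rnorm(100, 26, 1))
  expect_lt(period_change_test(big, ctrl)$p.value, 0.001)
})

test_that("circular statistics are wrap-aware", {
  expect_equal(circular_mean(c(0.9, 0.1)), 0)
  expect_equal(circular_mean(rep(0.37, 4)), 0.37)
  expect_equal(circular_sd(rep(0.37, 4)), 0)
  expect_error(circular_mean(numeric()), "non-empty")
  expect_warning(circular_mean(c(0, 0.5)), "undefined")

  # concentrated sample around 0.3 (wrapped normal ~ von Mises)
  set.seed(17)
  ph <- wrap_phase(0.3 + rnorm(500, 0, sqrt(1 / 5) / (2 * pi)))
  expect_lt(circ_dist(circular_mean(ph), 0.3), 0.02)

  cc <- circular_corr(ph, wrap_phase(ph + 0.25))
  expect_gt(cc$estimate, 0.9)
  expect_lt(cc$p.value, 1e-6)
  indep <- circular_corr(ph, wrap_phase(runif(500)))
  expect_gt(indep$p.value, 0.001)

  r <- rayleigh_test(runif(400))
  expect_gt(r$p.value, 0.01)
  expect_lt(rayleigh_test(ph)$p.value, 1e-6)
})

test_that("tidy and glance summarize fitted objects", {
  x <- seq(0, 0.99, by = 0.01)
  m <- fit_type1(pairs_dataset(x, x + 0.1 * sin(2 * pi * x)))
  td <- generics::tidy(m)
  expect_equal(td$term, c("a0", "a1", "b1", "a2", "b2"))
  gl <- generics::glance(m)
  expect_equal(gl$kind, "type1")
  expect_equal(gl$max_advance, 0.1, tolerance = 1e-6)
  m0 <- fit_type0(pairs_dataset(x, rep(0.3, length(x))))
  expect_equal(generics::glance(m0)$mean_final_phase, 0.3, tolerance = 1e-9)
  bt <- bootstrap_model_selection(pairs_dataset(x, rep(0.3, length(x))),
                                  B = 50, seed = 1)
  expect_s3_class(generics::tidy(bt), "tbl_df")
})
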