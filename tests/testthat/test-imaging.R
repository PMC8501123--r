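test_that("segmentation finds isolated nuclei with sub-pixel accuracy", {
  mv <- render_synthetic_movie(NULL, n_cells = 1, n_frames = 2, size = 96,
                               step_sd = 0, noise_sd = 0, seed = 2)
  seg <- segment_nuclei(mv$red[, , 1])
  expect_equal(nrow(seg$objects), 1)
  err <- sqrt((seg$objects$x - mv$truth$x[1])^2 +
                (seg$objects$y - mv$truth$y[1])^2)
  expect_lt(err, 1)
  # empty image is an empty frame, not an error
  empty <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(nrow(empty$objects), 0)
})

test_that("diameter gating and border exclusion are enforced", {
  # oversized nucleus (diameter 40 px > 35 gate) is rejected
  big <- render_synthetic_movie(NULL, n_cells = 1, n_frames = 1, size = 128,
                                diameter = 40, step_sd = 0, seed = 3)
  expect_equal(nrow(segment_nuclei(big$red[, , 1])$objects), 0)
  # nucleus centered on the border is excluded
  px <- seq_len(96)
  spot <- outer(exp(-(px - 1)^2 / 50), exp(-(px - 48)^2 / 50))
  expect_equal(nrow(segment_nuclei(spot + 0.01)$objects), 0)
})

test_that("background subtraction centers the outside-nuclei intensity", {
  img <- matrix(7, 50, 50)
  mask <- matrix(FALSE, 50, 50)
  mask[20:30, 20:30] <- TRUE
  out <- subtract_background(img, mask)
  expect_equal(mean(out[!mask]), 0)
  # background 5 + nucleus at 12: nucleus mean becomes 7
  img2 <- matrix(5, 50, 50)
  img2[mask] <- 12
  out2 <- subtract_background(img2, mask)
  expect_equal(mean(out2[mask]), 7)
  expect_error(subtract_background(img, !logical(2500)), "whole frame")
})

test_that("a static object yields one full-length track", {
  det <- tibble::tibble(frame = rep(1:30, 1), object = 1,
                        x = 50, y = 60, reporter = 1)
  trk <- track_centroids(det, 50, 24, 1)
  expect_equal(dplyr::n_distinct(trk$cell_id), 1)
  expect_equal(nrow(trk), 30)
})

test_that("links beyond the distance cap terminate tracks", {
  # both objects jump to fresh positions farther than the cap from anything
  det <- tibble::tibble(
    frame = c(1, 1, 2, 2),
    object = c(1, 2, 1, 2),
    x = c(0, 200, 400, 600), y = 0, reporter = 1
  )
  trk <- track_centroids(det, max_link_distance = 50, min_lifetime_h = 0)
  expect_equal(dplyr::n_distinct(trk$cell_id), 4) # tracks terminate, no jumps
  # whereas position exchange is within the cap and links crosswise
  swap <- tibble::tibble(frame = c(1, 1, 2, 2), object = c(1, 2, 1, 2),
                         x = c(0, 30, 30, 0), y = 0, reporter = 1)
  expect_equal(dplyr::n_distinct(track_centroids(swap, 50, 0)$cell_id), 2)
})

test_that("tracking is permutation-invariant to within-frame labels", {
  set.seed(12)
  n <- 8; nf <- 15
  x <- apply(matrix(rnorm(nf * n, 0, 4), nf, n), 2, cumsum) +
    rep(seq(20, 480, length.out = n), each = nf)
  det <- tibble::tibble(frame = rep(1:nf, n), object = rep(1:n, each = nf),
                        x = as.vector(x), y = rep(seq(20, 480, length.out = n),
                                                  each = nf),
                        reporter = rep(1:n, each = nf))
  perm <- det |> dplyr::group_by(frame) |> dplyr::slice_sample(prop = 1) |>
    dplyr::ungroup() |> dplyr::mutate(object = dplyr::row_number())
  t1 <- track_centroids(det, 50, 10, 1)
  t2 <- track_centroids(perm, 50, 10, 1)
  sig <- function(t) t |> dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(cell_id) |> dplyr::summarise(s = paste(reporter, collapse = ","))
  expect_setequal(sig(t1)$s, sig(t2)$s)
})

test_that("greedy linking recovers nearly all links for moderate motion", {
  set.seed(9)
  n <- 20; nf <- 40
  x <- matrix(0, nf, n); y <- matrix(0, nf, n)
  x[1, ] <- runif(n, 0, 500); y[1, ] <- runif(n, 0, 500)
  for (f in 2:nf) {
    x[f, ] <- x[f - 1, ] + runif(n, -10, 10)
    y[f, ] <- y[f - 1, ] + runif(n, -10, 10)
  }
  det <- tibble::tibble(frame = rep(1:nf, n), object = rep(1:n, each = nf),
                        x = as.vector(x), y = as.vector(y),
                        reporter = 1, true = rep(1:n, each = nf))
  trk <- track_centroids(det, 50, 24, 1)
  acc <- trk |> dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(ok = sum(head(true, -1) == tail(true, -1)))
  expect_gte(sum(acc$ok) / (n * (nf - 1)), 0.95)
})

test_that("tracks convert to trace tables with gap reporting", {
  det <- tibble::tibble(frame = c(1:30, setdiff(1:30, 10)),
                        object = rep(1:2, c(30, 29)),
                        x = 1, y = 1, reporter = 1,
                        cell_id = rep(c("t1", "t2"), c(30, 29)))
  expect_warning(tt <- tracks_to_table(det), "gap")
  expect_equal(unique(tt$cell_id), "t1")
  expect_equal(tt$time_h, 0:29)
  empty <- tracks_to_table(det[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the full front end reproduces traces up to an affine gain", {
  sim <- simulate_population(sim_config(
    n_cells = 10, duration = 47, cue_time = 24, measurement_noise_sd = 0,
    trend_base = 0, trend_rise = 0, gain_change = 0, amplitude_sd = 0, seed = 5
  ))
  mv <- render_synthetic_movie(sim$tracks, size = 400, step_sd = 2,
                               noise_sd = 0, min_separation = 70,
                               reporter_gain = 0.5, seed = 6)
  tt <- movie_to_tracks(mv, cue_time = 24)
  expect_equal(dplyr::n_distinct(tt$cell_id), 10)
  truthv <- matrix(mv$truth$reporter_true, nrow = 48)
  cors <- vapply(split(as.data.frame(tt), tt$cell_id), function(tr) {
    max(apply(truthv[tr$time_h + 1, , drop = FALSE], 2,
              function(g) stats::cor(tr$value, g)))
  }, 0)
  expect_gt(min(cors), 0.999)
})

test_that("zero reporter leaves the green channel at background", {
  flat <- track_table(data.frame(cell_id = rep(c("a", "b"), each = 10),
                                 time_h = rep(0:9, 2), value = 0),
                      cue_time = 5)
  mv <- render_synthetic_movie(flat, size = 128, step_sd = 0, noise_sd = 0,
                               reporter_base = 0, reporter_gain = 1, seed = 4)
  expect_equal(max(abs(mv$green - 0.05)), 0)
})
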