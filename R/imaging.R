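#' Render a synthetic two-channel nuclei movie
#'
#' Builds an image-stack fixture with known ground truth for the imaging
#' front end. Nuclei are soft-edged disks (radial logistic profile, edge
#' width ~1 px) performing a clipped random walk, so the measured equivalent
#' diameter of a segmented nucleus matches the nominal `diameter`;
#' the constitutive channel has constant per-cell brightness while the
#' reporter channel brightness follows the supplied per-cell traces
#' (affinely mapped to stay non-negative). Additive background and optional
#' Gaussian noise are applied to both channels.
#'
#' A warning is issued when the expected nucleus area exceeds `max_density`
#' of the frame area, since overlapping nuclei make the segmentation ground
#' truth ambiguous.
#'
#' @param tracks a [track_table()] whose values drive reporter brightness
#'   (one frame per grid timepoint), or `NULL` for a constant reporter.
#' @param n_cells number of nuclei (defaults to the number of traces).
#' @param n_frames number of frames (defaults to the trace grid length).
#' @param size frame side, pixels.
#' @param diameter nucleus diameter, pixels.
#' @param step_sd random-walk step SD per frame, pixels.
#' @param background additive background level.
#' @param noise_sd Gaussian pixel noise SD.
#' @param reporter_gain,reporter_base affine map from trace value to
#'   reporter brightness: `base + gain * value`, clipped at 0.
#' @param max_density overlap warning threshold (fraction of frame area).
#' @param min_separation minimal pairwise distance between initial nucleus
#'   centers, pixels (rejection-sampled); 0 places nuclei independently.
#'   Use a few diameters when the fixture requires unambiguous per-nucleus
#'   ground truth.
#' @param seed integer seed.
#' @return list with `red` and `green` arrays (`size x size x n_frames`),
#'   and `truth`: tibble `cell_id`, `frame`, `x`, `y`, `reporter_true`.
#' @export
render_synthetic_movie <- function(tracks = NULL, n_cells = NULL, n_frames = NULL,
                                   size = 192, diameter = 20, step_sd = 3,
                                   background = 0.05, noise_sd = 0,
                                   reporter_gain = 0.3, reporter_base = 1,
                                   max_density = 0.2, min_separation = 0,
                                   seed = 1L) {
  set.seed(seed)
  if (!is.null(tracks)) {
    grid <- sort(unique(tracks$time_h))
    ids <- sort(unique(tracks$cell_id))
    n_cells <- n_cells %||% length(ids)
    n_frames <- n_frames %||% length(grid)
    vals <- tracks |>
      as_tibble() |>
      arrange(.data$cell_id, .data$time_h) |>
      (\(d) matrix(d$value, nrow = length(grid), ncol = length(ids)))()
  } else {
    n_cells <- n_cells %||% 10
    n_frames <- n_frames %||% 30
    ids <- sprintf("cell%04d", seq_len(n_cells))
    vals <- matrix(0, n_frames, n_cells)
  }
  if (n_cells * (diameter^2) / size^2 > max_density) {
    warn("nucleus density above the overlap limit: tracking ground truth may be ambiguous")
  }
  radius <- diameter / 2
  margin <- diameter
  x <- matrix(0, n_frames, n_cells)
  y <- matrix(0, n_frames, n_cells)
  pos0 <- place_nuclei(n_cells, size, margin, min_separation)
  x[1, ] <- pos0$x
  y[1, ] <- pos0$y
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      x[f, ] <- pmin(pmax(x[f - 1, ] + rnorm(n_cells, 0, step_sd), margin), size - margin)
      y[f, ] <- pmin(pmax(y[f - 1, ] + rnorm(n_cells, 0, step_sd), margin), size - margin)
    }
  }
  bright <- pmax(reporter_base + reporter_gain * vals[seq_len(n_frames), , drop = FALSE], 0)

  px <- seq_len(size)
  red <- array(0, c(size, size, n_frames))
  green <- array(0, c(size, size, n_frames))
  for (f in seq_len(n_frames)) {
    rf <- matrix(background, size, size)
    gf <- matrix(background, size, size)
    for (i in seq_len(n_cells)) {
      r <- sqrt(outer((px - x[f, i])^2, (px - y[f, i])^2, "+"))
      spot <- stats::plogis((radius - r) / 1.2)
      rf <- rf + spot
      gf <- gf + bright[f, i] * spot
    }
    if (noise_sd > 0) {
      rf <- rf + rnorm(size^2, 0, noise_sd)
      gf <- gf + rnorm(size^2, 0, noise_sd)
    }
    red[, , f] <- rf
    green[, , f] <- gf
  }
  truth <- tibble(
    cell_id = rep(ids[seq_len(n_cells)], each = n_frames),
    frame = rep(seq_len(n_frames), n_cells),
    x = as.vector(x), y = as.vector(y),
    reporter_true = as.vector(bright)
  )
  list(red = red, green = green, truth = truth)
}

place_nuclei <- function(n, size, margin, min_separation) {
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    for (try in seq_len(500)) {
      xi <- runif(1, margin, size - margin)
      yi <- runif(1, margin, size - margin)
      if (i == 1 || min_separation <= 0 ||
          min(sqrt((x[seq_len(i - 1)] - xi)^2 + (y[seq_len(i - 1)] - yi)^2)) >= min_separation) {
        x[i] <- xi; y[i] <- yi
        break
      }
      if (try == 500) abort("cannot place nuclei at the requested min_separation")
    }
  }
  list(x = x, y = y)
}

#' Segment nuclei in one grayscale frame
#'
#' Simplified nuclei segmentation: band-pass (difference-of-Gaussians)
#' enhancement tuned to the expected feature width, Otsu global threshold on
#' the enhanced image, connected components, a diameter gate on the
#' equivalent diameter `2*sqrt(area/pi)`, and exclusion of objects touching
#' the frame border. An empty image yields an empty frame, not an error.
#'
#' @param img numeric matrix (single channel).
#' @param min_diameter,max_diameter diameter gate, pixels.
#' @param feature_width typical nucleus width for the band-pass, pixels.
#' @return list: `objects` (tibble `object`, `x`, `y`, `diameter`) and
#'   `mask` (logical matrix of gated in-frame nuclei pixels).
#' @export
segment_nuclei <- function(img, min_diameter = 9, max_diameter = 35,
                           feature_width = 25) {
  rng <- diff(range(img))
  if (rng < 1e-12) {
    return(list(objects = tibble(object = integer(), x = numeric(),
                                 y = numeric(), diameter = numeric()),
                mask = matrix(FALSE, nrow(img), ncol(img))))
  }
  enh <- EBImage::gblur(img, sigma = feature_width / 8) -
    EBImage::gblur(img, sigma = feature_width / 2)
  enh <- (enh - min(enh)) / diff(range(enh))
  bw <- enh > EBImage::otsu(EBImage::Image(enh))
  lab <- EBImage::bwlabel(bw)
  nobj <- max(lab)
  if (nobj == 0) {
    return(list(objects = tibble(object = integer(), x = numeric(),
                                 y = numeric(), diameter = numeric()),
                mask = matrix(FALSE, nrow(img), ncol(img))))
  }
  labm <- EBImage::imageData(lab)
  areas <- tabulate(labm[labm > 0], nbins = nobj)
  diam <- 2 * sqrt(areas / pi)
  cx <- vapply(seq_len(nobj), function(o) mean(row(labm)[labm == o]), 0)
  cy <- vapply(seq_len(nobj), function(o) mean(col(labm)[labm == o]), 0)
  border <- vapply(seq_len(nobj), function(o) {
    idx <- which(labm == o, arr.ind = TRUE)
    any(idx[, 1] %in% c(1, nrow(labm))) || any(idx[, 2] %in% c(1, ncol(labm)))
  }, TRUE)
  keep <- diam >= min_diameter & diam <= max_diameter & !border
  mask <- matrix(FALSE, nrow(img), ncol(img))
  if (any(keep)) mask[labm %in% which(keep)] <- TRUE
  list(objects = tibble(object = seq_len(sum(keep)),
                        x = cx[keep], y = cy[keep], diameter = diam[keep]),
       mask = mask)
}

#' Background subtraction outside nuclei
#'
#' Subtracts the mean intensity over the mask complement (pixels outside
#' nuclei) from the whole image; output values may be negative.
#'
#' @param img numeric matrix (reporter channel).
#' @param mask logical matrix of nuclei pixels from the same frame.
#' @return corrected numeric matrix.
#' @export
subtract_background <- function(img, mask) {
  if (all(mask)) abort("mask covers the whole frame: no background estimate")
  img - mean(img[!mask])
}

#' Measure per-frame nuclei intensities
#'
#' Runs [segment_nuclei()] on the constitutive channel and measures, per
#' object, the mean constitutive intensity and the mean background-corrected
#' reporter intensity (see [subtract_background()]).
#'
#' @param red,green numeric matrices: constitutive and reporter channels of
#'   one frame.
#' @param ... passed to [segment_nuclei()].
#' @return tibble `object`, `x`, `y`, `diameter`, `constitutive`,
#'   `reporter`.
#' @export
measure_frame <- function(red, green, ...) {
  seg <- segment_nuclei(red, ...)
  if (nrow(seg$objects) == 0) {
    return(mutate(seg$objects, constitutive = numeric(0), reporter = numeric(0)))
  }
  gcorr <- subtract_background(green, seg$mask)
  lab <- EBImage::imageData(EBImage::bwlabel(seg$mask))
  # bwlabel on the gated mask relabels 1..K in the same spatial order used
  # for the object table (row-major component discovery)
  obj <- seg$objects
  obj$constitutive <- vapply(seq_len(nrow(obj)), function(o) mean(red[lab == o]), 0)
  obj$reporter <- vapply(seq_len(nrow(obj)), function(o) mean(gcorr[lab == o]), 0)
  obj
}

#' Greedy nearest-neighbour centroid tracking
#'
#' Links objects frame to frame by ascending pairwise displacement subject
#' to a hard distance cap: candidate links are sorted by distance and
#' accepted greedily (ties broken by smaller displacement, then lower object
#' index); unmatched objects terminate or start tracks. Tracks shorter than
#' the minimum lifetime are dropped.
#'
#' @param frames tibble of per-frame detections with columns `frame`,
#'   `object`, `x`, `y` and any per-object measurements (carried through).
#' @param max_link_distance cap on per-frame displacement, pixels.
#' @param min_lifetime_h minimal track lifetime, hours.
#' @param sampling_interval hours per frame.
#' @return tibble of the input rows annotated with `cell_id`, restricted to
#'   tracks meeting the lifetime filter.
#' @export
track_centroids <- function(frames, max_link_distance = 50, min_lifetime_h = 24,
                            sampling_interval = 1) {
  if (nrow(frames) == 0) return(mutate(frames, cell_id = character(0)))
  frames <- arrange(as_tibble(frames), .data$frame, .data$object)
  frame_ids <- sort(unique(frames$frame))
  frames$track <- NA_integer_
  next_track <- 1L
  prev_idx <- which(frames$frame == frame_ids[1])
  frames$track[prev_idx] <- seq_along(prev_idx)
  next_track <- length(prev_idx) + 1L
  for (k in seq_along(frame_ids)[-1]) {
    cur_idx <- which(frames$frame == frame_ids[k])
    if (length(cur_idx) == 0) { prev_idx <- cur_idx; next }
    if (length(prev_idx) > 0) {
      dx <- outer(frames$x[prev_idx], frames$x[cur_idx], "-")
      dy <- outer(frames$y[prev_idx], frames$y[cur_idx], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dist[cand], cand[, 1], cand[, 2])
        used_prev <- logical(length(prev_idx))
        used_cur <- logical(length(cur_idx))
        for (ci in ord) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (!used_prev[i] && !used_cur[j]) {
            frames$track[cur_idx[j]] <- frames$track[prev_idx[i]]
            used_prev[i] <- TRUE
            used_cur[j] <- TRUE
          }
        }
      }
    }
    new <- cur_idx[is.na(frames$track[cur_idx])]
    if (length(new) > 0) {
      frames$track[new] <- seq(next_track, length.out = length(new))
      next_track <- next_track + length(new)
    }
    prev_idx <- cur_idx
  }
  life <- frames |>
    count(.data$track, name = "n_frames") |>
    mutate(lifetime_h = (.data$n_frames - 1) * sampling_interval)
  keep <- life$track[life$lifetime_h >= min_lifetime_h]
  frames |>
    filter(.data$track %in% keep) |>
    mutate(cell_id = sprintf("track%04d", .data$track)) |>
    select(-"track")
}

#' Convert centroid tracks to a track table
#'
#' One trace per track with times from `frame * sampling_interval` (frame 1
#' = 0 h) and values from the background-corrected reporter means. Tracks
#' with internal frame gaps are excluded and reported in the `gap_report`
#' attribute.
#'
#' @param tracks output of [track_centroids()] (needs a `reporter` column).
#' @param sampling_interval hours per frame.
#' @param cue_time optional cue time, hours.
#' @return a [track_table()].
#' @export
tracks_to_table <- function(tracks, sampling_interval = 1, cue_time = NA_real_) {
  if (nrow(tracks) == 0) {
    return(track_table(tibble(cell_id = character(), time_h = numeric(),
                              value = numeric()),
                       cue_time = cue_time, sampling_interval = sampling_interval))
  }
  gaps <- tracks |>
    group_by(.data$cell_id) |>
    summarise(gap = any(diff(sort(.data$frame)) != 1), .groups = "drop") |>
    filter(.data$gap)
  if (nrow(gaps) > 0) {
    warn(paste0("track(s) with frame gaps excluded: ",
                paste(gaps$cell_id, collapse = ", ")))
  }
  df <- tracks |>
    filter(!.data$cell_id %in% gaps$cell_id) |>
    mutate(time_h = (.data$frame - 1) * sampling_interval) |>
    select("cell_id", "time_h", value = "reporter")
  out <- track_table(df, cue_time = cue_time, sampling_interval = sampling_interval)
  attr(out, "gap_report") <- gaps
  out
}

#' Run the full imaging front end on a movie
#'
#' Segment, background-correct and measure every frame, then track and
#' convert to a [track_table()].
#'
#' @param movie list with `red` and `green` arrays as produced by
#'   [render_synthetic_movie()].
#' @param sampling_interval hours per frame.
#' @param cue_time optional cue time, hours.
#' @param max_link_distance,min_lifetime_h tracking parameters.
#' @param ... passed to [segment_nuclei()].
#' @return a [track_table()] of background-corrected reporter traces.
#' @export
movie_to_tracks <- function(movie, sampling_interval = 1, cue_time = NA_real_,
                            max_link_distance = 50, min_lifetime_h = 24, ...) {
  n_frames <- dim(movie$red)[3]
  frames <- map(seq_len(n_frames), function(f) {
    m <- measure_frame(movie$red[, , f], movie$green[, , f], ...)
    mutate(m, frame = f)
  }) |> list_rbind()
  tr <- track_centroids(frames, max_link_distance = max_link_distance,
                        min_lifetime_h = min_lifetime_h,
                        sampling_interval = sampling_interval)
  tracks_to_table(tr, sampling_interval = sampling_interval, cue_time = cue_time)
}
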