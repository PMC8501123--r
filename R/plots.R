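#' Plot a PTC or PRC
#'
#' Double-plotted scatter of the phase pairs, optionally overlaid with
#' fitted resetting-model curves.
#'
#' @param object a `ptc_dataset`.
#' @param type `"ptc"` (new phase vs old phase) or `"prc"` (shift vs old
#'   phase).
#' @param models optional list of `resetting_model`s to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ptc_dataset <- function(object, type = c("ptc", "prc"), models = NULL, ...) {
  type <- match.arg(type)
  pts <- double_plot(object, type)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$old_phase, y = .data$y,
                                         alpha = !.data$copy)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.9, `FALSE` = 0.25)) +
    ggplot2::labs(
      x = "old phase (cycles)",
      y = if (type == "ptc") "new phase (cycles)" else "phase shift (cycles)",
      title = sprintf("%s | %s | n = %d", toupper(type),
                      attr(object, "treatment") %||% "", nrow(object))
    ) +
    ggplot2::theme_minimal()
  if (type == "ptc") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50")
  } else {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50")
  }
  if (!is.null(models)) {
    if (inherits(models, "resetting_model")) models <- list(models)
    xg <- seq(0, 1, by = 0.005)
    curves <- map(models, function(m) {
      yy <- if (type == "ptc") predict(m, xg, "new_phase") else predict(m, xg, "shift")
      tibble(x = c(xg, xg + 1),
             y = rep(yy, 2) + if (type == "ptc") rep(c(0, 1), each = length(xg)) else 0,
             kind = m$kind)
    }) |> list_rbind()
    p <- p + ggplot2::geom_point(
      data = curves, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind),
      inherit.aes = FALSE, size = 0.3
    )
  }
  p
}

#' Dose-by-phase heat map of binned new phases
#'
#' Visualizes the output of [bin_phase_plane()]: old-phase bins on x, dose
#' on y, circular-mean new phase as fill. Discontinuities along a row flag
#' the neighbourhood of a phase singularity.
#'
#' @param binned tibble from [bin_phase_plane()].
#' @return a ggplot object.
#' @export
plot_phase_plane <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$old_bin, y = factor(.data$dose),
                                       fill = .data$new_phase_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2c7bb6", "#ffffbf", "#d7191c", "#2c7bb6"),
      limits = c(0, 1), na.value = "grey80"
    ) +
    ggplot2::labs(x = "old phase (cycles)", y = "dose",
                  fill = "mean new phase") +
    ggplot2::theme_minimal()
}

#' Fitted resetting-model curve
#'
#' @param object a `resetting_model`.
#' @param type `"ptc"` or `"prc"` coordinates.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.resetting_model <- function(object, type = c("ptc", "prc"), ...) {
  type <- match.arg(type)
  xg <- seq(0, 1, by = 0.002)
  yy <- if (type == "ptc") predict(object, xg, "new_phase") else predict(object, xg, "shift")
  ggplot2::ggplot(tibble(x = xg, y = yy), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "old phase (cycles)",
                  y = if (type == "ptc") "predicted new phase" else "predicted shift",
                  title = paste0(object$kind, " model")) +
    ggplot2::theme_minimal()
}
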