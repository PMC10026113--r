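# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic brightfield scene
#'
#' @param object A [make_cell_scene()] scene.
#' @param truth Overlay the ground-truth cell outlines.
#' @param ... Ignored.
#' @return A ggplot raster of the image.
#' @export
autoplot.cell_scene <- function(object, truth = TRUE, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$image)),
                           col = seq_len(ncol(object$image)))
  df$intensity <- as.numeric(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (truth && nrow(object$truth_params))
    p <- p + ggplot2::geom_point(
      data = object$truth_params,
      ggplot2::aes(.data$col, .data$row), inherit.aes = FALSE,
      colour = "red", shape = 3)
  p
}

#' Plot a plate-assay standard curve
#'
#' @param object A [fit_standard_curve()] object.
#' @param samples Optional [interpolate_samples()] result to overlay.
#' @param ... Ignored.
#' @return A ggplot of blank-corrected OD against log10 concentration.
#' @export
autoplot.standard_curve <- function(object, samples = NULL, ...) {
  p <- ggplot2::ggplot(object$knots,
                       ggplot2::aes(.data$log_conc, .data$od)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log10 concentration (mU/mL)",
                  y = "blank-corrected OD",
                  title = "Serial-dilution standard curve") +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    ok <- samples[samples$flag == "ok", ]
    if (nrow(ok))
      p <- p + ggplot2::geom_point(
        data = mutate(ok, log_conc = log10(.data$conc)),
        ggplot2::aes(.data$log_conc, .data$od),
        colour = "#B2182B", shape = 17, size = 2)
  }
  p
}

#' Plot tracks of a time-lapse
#'
#' @param object A [track_objects()] table.
#' @param ... Ignored.
#' @return A ggplot of per-track trajectories in image coordinates.
#' @export
autoplot.track_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$col, .data$row,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "track", x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}
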