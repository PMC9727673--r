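# ggplot2 views of the main result types.

#' @describeIn run_prioritization Map of the priority ranking (requires the
#'   feature set to carry its grid).
#' @param object A `priority_rank`.
#' @method autoplot priority_rank
#' @export
autoplot.priority_rank <- function(object, ...) {
  grid <- object$features$grid
  if (is.null(grid)) abort("feature set carries no grid; cannot map")
  df <- grid |> inner_join(object$rank, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$priority)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "priority") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Priority rank map (%s)", object$rule),
                  x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Map a per-cell layer
#'
#' Quick tile map of any per-cell value (local PD, HMI, PA fraction, ...).
#'
#' @param layer Tibble with `cell_id` and the value column.
#' @param grid Grid tibble.
#' @param value Name of the value column.
#' @return A ggplot object.
#' @export
plot_cell_layer <- function(layer, grid, value) {
  df <- grid |> inner_join(layer, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot feature retention curves
#'
#' Retention of each feature (and their mean, drawn thick) against the
#' fraction of the landscape removed.
#'
#' @param curves Long tibble from [performance_curves()].
#' @param max_features Subsample at most this many individual curves.
#' @return A ggplot object.
#' @export
plot_performance_curves <- function(curves, max_features = 50) {
  feats <- unique(curves$feature)
  if (length(feats) > max_features) {
    feats <- feats[seq(1, length(feats), length.out = max_features)]
  }
  mean_curve <- curves |>
    group_by(.data$f) |>
    summarise(retention = mean(.data$retention), .groups = "drop")
  ggplot2::ggplot(curves |> filter(.data$feature %in% feats),
                  ggplot2::aes(.data$f, .data$retention,
                               group = .data$feature)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::geom_line(data = mean_curve, ggplot2::aes(group = NULL),
                       linewidth = 1, colour = "firebrick") +
    ggplot2::labs(x = "fraction of landscape removed",
                  y = "feature retention") +
    ggplot2::theme_minimal()
}
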