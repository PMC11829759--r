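#' Plot a neighbourhood expression map
#'
#' Scatter of the reference points in two chosen axes, coloured by the
#' neighbourhood-averaged attribute; unsupported points are hollow.
#'
#' @param object A `neighborhood_map` from [average_neighborhood()].
#' @param axes Two coordinate column names to plot (default anteroposterior
#'   x against dorsoventral y).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neighborhood_map
#' @export
autoplot.neighborhood_map <- function(object, axes = c("x_um", "y_um"), ...) {
  supported <- dplyr::filter(object, .data$support > 0)
  empty <- dplyr::filter(object, .data$support == 0)
  ggplot2::ggplot(supported,
                  ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$value), size = 2) +
    ggplot2::geom_point(data = empty, shape = 1, colour = "grey60", size = 2) +
    ggplot2::scale_colour_viridis_c(name = attr(object, "attribute")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste(axes[1]), y = paste(axes[2]),
      title = sprintf("Neighbourhood average (radius %g um)",
                      attr(object, "radius_um"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot MSD curves for a set of tracks
#'
#' Log-log MSD against lag, one line per track, with reference slopes 1
#' (diffusive) and 2 (ballistic).
#'
#' @param tracks A `track_set` tibble.
#' @param max_lag_fraction Passed to [msd_curve()].
#' @return A ggplot object.
#' @export
plot_msd_curves <- function(tracks, max_lag_fraction = 0.5) {
  curves <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      dplyr::mutate(msd_curve(g, max_lag_fraction), track_id = key$track_id)
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$msd_um2 > 0)
  ggplot2::ggplot(curves, ggplot2::aes(.data$lag_s, .data$msd_um2,
                                       group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Plot track directionality against distance from the ablation
#'
#' MSD exponent per track against its start distance to the ablation centre
#' (or control point), with the directionality threshold drawn as a dashed
#' line.
#'
#' @param metrics A tibble from [track_metrics()].
#' @param alpha_threshold Threshold line (default 1.1).
#' @return A ggplot object.
#' @export
plot_track_directionality <- function(metrics, alpha_threshold = 1.1) {
  ggplot2::ggplot(metrics, ggplot2::aes(.data$start_distance_um, .data$alpha)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$directional), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = alpha_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "start distance to ablation centre (um)",
                  y = "MSD exponent", colour = "directional") +
    ggplot2::theme_minimal()
}

#' Plot per-segment tissue lengths
#'
#' @param object A `tissue_lengths` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_lengths
#' @export
autoplot.tissue_lengths <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$length_um)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "segment (somite order)", y = "length (um)",
                  title = object$tissue) +
    ggplot2::theme_minimal()
}
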