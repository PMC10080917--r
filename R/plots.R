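#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity profile with its detected AIS span
#'
#' Reproduces the standard presentation of the method: the raw profile in
#' grey, the background-subtracted smoothed profile in black, and the
#' detected AIS span as a shaded region between the half-of-range
#' crossings.
#'
#' @param profile Profile tibble for a single neuron.
#' @param config A [bounds_config()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, config = bounds_config()) {
  curves <- pipeline_curves(profile, config)
  meas <- quantify_ais(profile, config)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$distance_um)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::labs(x = "Distance from soma (µm)", y = "Intensity (au)",
                  title = profile$neuron_id[1]) +
    ggplot2::theme_classic()
  if (meas$status[1] == "determined") {
    p <- p + ggplot2::annotate(
      "rect", xmin = meas$start_um, xmax = meas$start_um + meas$length_um,
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "seagreen"
    )
  }
  p
}

#' @rdname aismorph-autoplot
#' @export
autoplot.ais_scene <- function(object, ...) {
  ny <- nrow(object$fill)
  nx <- ncol(object$fill)
  df <- tidyr::expand_grid(y = seq_len(ny) - 1, x = seq_len(nx) - 1)
  df$fill_ch <- as.vector(object$fill)
  df$marker_ch <- as.vector(object$marker)
  long <- tidyr::pivot_longer(df, c("fill_ch", "marker_ch"),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' Autoplot methods
#'
#' @param object A package result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name aismorph-autoplot
NULL

#' @rdname aismorph-autoplot
#' @export
autoplot.dimension_summary <- function(object, ...) {
  long <- object$replicate_means |>
    tidyr::pivot_longer(c("mean_start_um", "mean_length_um"),
                        names_to = "measure", values_to = "um")
  ggplot2::ggplot(long, ggplot2::aes(.data$localization_class, .data$um,
                                     colour = .data$group_label)) +
    ggplot2::geom_jitter(width = 0.12, height = 0) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "µm (replicate means)") +
    ggplot2::theme_classic()
}

#' Stacked bar chart of localization proportions
#'
#' @param proportions Output of [localization_proportions()].
#' @return A ggplot object.
#' @export
plot_localization_proportions <- function(proportions) {
  long <- proportions |>
    dplyr::select("group_label", dplyr::starts_with("raw_pct_")) |>
    tidyr::pivot_longer(-"group_label", names_to = "class",
                        names_prefix = "raw_pct_", values_to = "pct")
  long$class <- factor(long$class, levels = c("multi", "acd", "direct"))
  ggplot2::ggplot(long, ggplot2::aes(.data$group_label, .data$pct,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Cells (%)", fill = "AIS localization") +
    ggplot2::theme_classic()
}
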