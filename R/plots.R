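# ggplot2 views of the main result types.

#' Spatial map of pseudotime over a section
#'
#' @param section a [section_dataset].
#' @param pseudotime output of [compute_pseudotime()].
#' @return a ggplot: spots at their coordinates coloured by pseudotime,
#'   unreached spots in grey.
#' @export
plot_pseudotime <- function(section, pseudotime) {
  df <- section$spots |>
    left_join(pseudotime[, c("barcode", "pseudotime")], by = "barcode")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   colour = .data$pseudotime)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = section$section_id, x = "x (um)", y = "y (um)",
                  colour = "pseudotime") +
    ggplot2::theme_minimal()
}

#' Density dynamics across time points
#'
#' @param density tibble as from [communication_density()]`$density`.
#' @param timepoint_order optional explicit ordering of time points.
#' @return a ggplot: per-pair densities (points) and the per-time-point
#'   mean (line) for each trajectory.
#' @export
plot_density_dynamics <- function(density, timepoint_order = NULL) {
  if (!is.null(timepoint_order)) {
    density <- density |>
      mutate(timepoint = factor(.data$timepoint, levels = timepoint_order))
  }
  means <- density |>
    group_by(.data$trajectory_id, .data$timepoint) |>
    summarise(density = mean(.data$density), .groups = "drop")
  ggplot2::ggplot(density, ggplot2::aes(.data$timepoint, .data$density)) +
    ggplot2::geom_point(alpha = 0.6, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1)) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trajectory_id)) +
    ggplot2::labs(y = "communication density", x = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of subtype similarities across time points
#'
#' @param similarity tibble with columns `timepoint_a`, `timepoint_b`,
#'   `similarity` (and optionally `trajectory_id` for facetting).
#' @return a ggplot tile map.
#' @export
plot_subtype_similarity <- function(similarity) {
  p <- ggplot2::ggplot(similarity,
                       ggplot2::aes(.data$timepoint_a, .data$timepoint_b,
                                    fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$similarity)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal()
  if ("trajectory_id" %in% names(similarity)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$trajectory_id))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.trajectory3d_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$support,
                                   stats::reorder(.data$chain_str,
                                                  .data$support),
                                   fill = .data$bundle)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$timepoint)) +
    ggplot2::labs(x = "supporting sections", y = NULL, fill = "bundle") +
    ggplot2::theme_minimal()
}
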