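# ggplot2 visualisations for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.climate_grid <- function(object, layers = names(object$layers), ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(layers), names_to = "layer") |>
    dplyr::mutate(layer = factor(.data$layer, levels = bio_variables()))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$label, x = NULL, y = NULL, fill = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.suitability_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s -- %s", object$species_id, object$label),
                  x = "col", y = "row", fill = "suitability")
}

#' @exportS3Method ggplot2::autoplot
autoplot.richness_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Species richness -- %s", object$label),
                  x = "col", y = "row", fill = "richness")
}

#' @exportS3Method ggplot2::autoplot
autoplot.zone_set <- function(object, ...) {
  ggplot2::ggplot(zone_cells(object),
                  ggplot2::aes(.data$col, .data$row,
                               fill = factor(.data$zone_id))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Zones (%s)", object$level),
                  x = "col", y = "row")
}

#' Distribution of per-species AUC with performance-class cut points
#'
#' @param species_metrics per-species metrics tibble (needs an `auc` column).
#' @return a ggplot object.
#' @export
plot_performance <- function(species_metrics) {
  stopifnot("auc" %in% names(species_metrics))
  ggplot2::ggplot(species_metrics, ggplot2::aes(.data$auc)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7, 0.8, 0.9),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean AUC", y = "species")
}

#' Per-zone richness change between baseline and a scenario
#'
#' @param change result of [richness_change()].
#' @return a ggplot object (diverging bar chart of zone deltas).
#' @export
plot_richness_change <- function(change) {
  stopifnot(is.list(change), "deltas" %in% names(change))
  df <- dplyr::arrange(change$deltas, .data$delta)
  df$name <- factor(df$name, levels = df$name)
  ggplot2::ggplot(df, ggplot2::aes(.data$name, .data$delta,
                                   fill = .data$delta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "change in zone species count")
}
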