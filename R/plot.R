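#' Map a diversity surface
#'
#' Tile map of per-cell values, faceted by metric (and group when several
#' are present).
#'
#' @param object a `div_surface` tibble with centroid coordinates
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.div_surface <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
  n_metric <- length(unique(object$metric))
  n_group <- length(unique(object$group))
  if (n_metric > 1 && n_group > 1)
    p <- p + ggplot2::facet_grid(group ~ metric)
  else if (n_metric > 1)
    p <- p + ggplot2::facet_wrap(~metric, scales = "free")
  else if (n_group > 1)
    p <- p + ggplot2::facet_wrap(~group)
  p
}

canape_palette <- c(
  "not-significant" = "grey85",
  "neo" = "#d7191c",
  "paleo" = "#2c7bb6",
  "mixed" = "#abdda4",
  "super" = "#5e3c99"
)

#' Map a CANAPE classification
#'
#' Tile map of the per-cell endemism categories.
#'
#' @param object a `canape_map` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.canape_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$category)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = canape_palette, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = "endemism")
}

#' Map per-cell fuzzy similarity between two surfaces
#'
#' @param object a `group_similarity` result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.group_similarity <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}
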