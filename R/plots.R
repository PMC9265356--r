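raster_tibble <- function(r) {
  d <- dim(r$values)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(r$values)
  ) |>
    dplyr::filter(.data$value != r$nodata, !is.na(.data$value))
}

#' Plot a categorical raster
#'
#' @param object a [land_raster()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot land_raster
#' @export
autoplot.land_raster <- function(object, ...) {
  df <- raster_tibble(object)
  cls <- object$classes
  if (!is.null(cls)) {
    df$value <- factor(df$value, levels = unname(cls), labels = names(cls))
  } else {
    df$value <- factor(df$value)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot conflict levels per evaluation unit
#'
#' One panel per date, tiles colored by the five conflict levels.
#'
#' @param object a `conflict_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot conflict_result
#' @export
autoplot.conflict_result <- function(object, ...) {
  u <- object$units
  u$level_name <- factor(conflict_level_names()[u$level],
                         levels = conflict_level_names())
  ggplot2::ggplot(u, ggplot2::aes(.data$ucol, -.data$urow,
                                  fill = .data$level_name)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~date) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               drop = FALSE) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "conflict level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot per-level conflict shares over dates
#'
#' @param result a `conflict_result`.
#' @return A ggplot bar chart of level percentages by date.
#' @export
plot_conflict_shares <- function(result) {
  s <- summarize_conflict(result)
  s$level_name <- factor(s$level_name, levels = conflict_level_names())
  ggplot2::ggplot(s, ggplot2::aes(.data$date, .data$pct,
                                  fill = .data$level_name)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    ggplot2::labs(x = NULL, y = "% of evaluation units",
                  fill = "conflict level") +
    ggplot2::theme_minimal()
}

#' Plot functional zones
#'
#' @param zoning the `zoning` element of a [run_pipeline()] result (or any
#'   list with `zones` and a `raster`).
#' @return A ggplot of zone tiles.
#' @export
plot_zones <- function(zoning) {
  autoplot.land_raster(zoning$raster)
}
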