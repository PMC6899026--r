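# Presentation surfaces: binary spatial maps and percent-correlated bar
# summaries. Every saved figure has a CSV twin, so no number exists only in
# a plot.

#' @importFrom rlang .data
NULL

#' Binary spatial map of correlated/uncorrelated cells
#'
#' Scatter of cell centroids, one panel per FOV, colored by the spatial
#' classification (uncorrelated purple, correlated green by convention).
#' The y axis is reversed to match the image convention (origin top-left).
#'
#' @param scored classified score table (one condition, or facet over more).
#' @param colors named vector with entries `uncorrelated` and `correlated`.
#' @return a ggplot object; unscored cells are omitted (a warning reports if
#'   no cell is scored).
#' @export
plot_spatial_map <- function(scored,
                             colors = c(uncorrelated = "purple",
                                        correlated = "green4")) {
  keep <- !is.na(scored$correlated_flag)
  if (!any(keep)) warning("no scored cells: empty panel")
  df <- scored[keep, , drop = FALSE]
  df$status <- factor(ifelse(df$correlated_flag, "correlated", "uncorrelated"),
                      levels = c("uncorrelated", "correlated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                   color = .data$status)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = unname(colors[c("uncorrelated", "correlated")]),
                                breaks = c("uncorrelated", "correlated"),
                                drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~fov_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Percent-correlated bar summary across conditions
#'
#' Grouped bars of the percentage of spatially correlated cells by time
#' point, vehicle/treated side by side (blue/orange by convention), faceted
#' by cell type.
#'
#' @param summary output of [percent_correlated()].
#' @param colors named vector keyed by treatment level; unnamed treatments
#'   get default hues.
#' @return a ggplot object.
#' @export
plot_percent_correlated <- function(summary,
                                    colors = c(vehicle = "steelblue",
                                               `IGF-1` = "darkorange")) {
  df <- summary
  df$time_point <- factor(df$time_point, levels = sort(unique(df$time_point)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_point,
                                        y = .data$percent_correlated,
                                        fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "time (min)", y = "% spatially correlated cells",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (all(unique(df$treatment) %in% names(colors))) {
    p <- p + ggplot2::scale_fill_manual(values = colors)
  }
  p
}

#' Save a summary figure with its CSV twin
#'
#' @param summary output of [percent_correlated()].
#' @param dir output directory (created if needed).
#' @param name base file name (without extension).
#' @param width,height device size in inches.
#' @return named character vector with the `csv` and `png` paths, invisibly.
#' @export
summary_report <- function(summary, dir, name = "percent_correlated",
                           width = 7, height = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  png <- file.path(dir, paste0(name, ".png"))
  write_table(summary, csv)
  ggplot2::ggsave(png, plot_percent_correlated(summary),
                  width = width, height = height, dpi = 150)
  invisible(c(csv = csv, png = png))
}

#' Save a spatial map figure with its CSV twin
#'
#' @param scored classified score table.
#' @param dir output directory.
#' @param name base file name.
#' @param width,height device size in inches.
#' @return named character vector with the `csv` and `png` paths, invisibly.
#' @export
spatial_map_report <- function(scored, dir, name = "spatial_map",
                               width = 8, height = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  png <- file.path(dir, paste0(name, ".png"))
  write_table(scored, csv)
  ggplot2::ggsave(png, plot_spatial_map(scored),
                  width = width, height = height, dpi = 150)
  invisible(c(csv = csv, png = png))
}
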