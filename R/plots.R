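# ggplot2 views of simulation states and metric series.

#' Plot a simulation state
#'
#' Polygons for vertex-model and Voronoi states, tiles for lattices, points
#' for overlapping-spheres populations, filled by cell type.
#'
#' @param state A simulation state (e.g. `run_simulation(...)$state`).
#' @return A ggplot object.
#' @export
plot_tissue <- function(state) {
  g <- frame_geometry(state)
  type <- factor(g$cell_data[["Cell types"]])
  if (all(g$cell_types == VTK_VERTEX)) {
    df <- data.frame(x = g$points[, 1], y = g$points[, 2], type = type)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$type)) +
      ggplot2::geom_point(size = 3)
  } else {
    df <- do.call(rbind, lapply(seq_along(g$cells), function(i) {
      idx <- g$cells[[i]]
      data.frame(x = g$points[idx, 1], y = g$points[idx, 2],
                 cell = i, type = type[i])
    }))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$cell,
                                          fill = .data$type)) +
      ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(fill = "Cell type", colour = "Cell type")
}

#' Plot metric time series of a run
#'
#' @param sim A `tissue_simulation` from [run_simulation()].
#' @param metric Column of `sim$metrics` to plot (default: all numeric
#'   metric columns, facetted).
#' @return A ggplot object.
#' @export
plot_metrics <- function(sim, metric = NULL) {
  m <- sim$metrics
  cols <- setdiff(names(m), "t")
  if (!is.null(metric)) cols <- intersect(cols, metric)
  long <- do.call(rbind, lapply(cols, function(cl) {
    data.frame(t = m$t, metric = cl, value = as.numeric(m[[cl]]))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time", y = NULL)
}
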