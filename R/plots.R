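# Plot methods for the pipeline's result objects.

#' Plot a label map
#'
#' @param object a `label_map`.
#' @param ... ignored.
#' @return a ggplot raster of the per-pixel scene classes.
#' @method autoplot label_map
#' @export
autoplot.label_map <- function(object, ...) {
  df <- tidy.label_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(NUCLEUS = "#2c2c54",
                                          CYTOPLASM = "#c2a5cf",
                                          BACKGROUND = "#f7f7f7",
                                          DEBRIS = "#b2182b")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Scene class")
}

#' Plot a cluster-count selection curve
#'
#' @param object a `cluster_count_report` from [choose_cluster_count()].
#' @param ... ignored.
#' @method autoplot cluster_count_report
#' @export
autoplot.cluster_count_report <- function(object, ...) {
  chosen <- attr(object, "chosen")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$clusters, y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Clusters", y = "CV error",
                  title = sprintf("Cluster-count selection (chosen: %d)", chosen))
}
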