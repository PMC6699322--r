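# ggplot2 visualization methods for the result containers.

slice_plot_base <- function(df, fill, slice = NULL) {
  if (!is.null(slice)) df <- dplyr::filter(df, .data$slice %in% !!slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = {{ fill }})) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~ slice, labeller = ggplot2::label_both) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a detection map
#' @param object a `detection_map`.
#' @param slice slice indices to show (default all).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.detection_map <- function(object, slice = NULL, ...) {
  slice_plot_base(tidy.detection_map(object), .data$response, slice) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "response", title = object$detector)
}

#' Plot one parameter map
#' @param object a `param_maps` object.
#' @param parameter one of `"adc"`, `"slope"`, `"d"`, `"dstar"`, `"pf"`.
#' @param slice slice indices to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.param_maps <- function(object, parameter = "d", slice = NULL, ...) {
  parameter <- match.arg(parameter, c("adc", "slope", "d", "dstar", "pf"))
  df <- tidy.param_maps(object)
  df$value <- df[[parameter]]
  df$value[!df$valid] <- NA
  slice_plot_base(df, .data$value, slice) +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::labs(fill = parameter)
}

#' Plot a tissue label map
#'
#' Central tumor in red and peripheral tumor in green, following the usual
#' lesion-overlay convention; cyst blue, normal grey.
#'
#' @param object a `tissue_labels` map.
#' @param slice slice indices to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_labels <- function(object, slice = NULL, ...) {
  df <- tidy.tissue_labels(object)
  df$tissue <- factor(df$tissue, levels = names(object$levels))
  pal <- c(background = "black", normal = "grey70", cyst = "royalblue",
           tumor_central = "red", tumor_peripheral = "green3",
           other = "orange")
  slice_plot_base(df, .data$tissue, slice) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(fill = "tissue")
}

#' Plot per-class parameter distributions of a labeled case
#'
#' Boxplots of a fitted parameter by tissue class -- the phantom-cohort
#' analogue of per-patient median boxplots.
#'
#' @param labels a `tissue_labels` map.
#' @param maps a `param_maps` object on the same grid.
#' @param parameter which parameter to plot.
#' @return A ggplot object.
#' @export
plot_class_boxplots <- function(labels, maps, parameter = "d") {
  parameter <- match.arg(parameter, c("adc", "slope", "d", "dstar", "pf"))
  df <- tidy.param_maps(maps) |>
    dplyr::mutate(tissue = tidy.tissue_labels(labels)$tissue) |>
    dplyr::filter(.data$valid, !.data$tissue %in% c("background", "other"))
  df$value <- df[[parameter]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = parameter)
}
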