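# ggplot2 graphics for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a separability matrix
#'
#' Feature-by-period tile map of the Jeffries-Matusita distance, the
#' standard way of eyeballing which features separate the class pair in
#' which part of the season.
#'
#' @param object A [separability_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot separability_matrix
#' @export
autoplot.separability_matrix <- function(object, ...) {
  cp <- attr(object, "class_pair")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_doy, y = .data$feature,
                                   fill = .data$jm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2), name = "J-M") +
    ggplot2::labs(x = "Day of year (period midpoint)", y = NULL,
                  title = paste("J-M separability:", cp[1], "vs", cp[2])) +
    ggplot2::theme_minimal()
}

#' Trace plot of an automatic threshold search
#'
#' Precision, recall and F1 against the evaluated thresholds, with the
#' accepted iterates marked.
#'
#' @param object A `threshold_result` from [iterative_threshold()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_result
#' @export
autoplot.threshold_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::geom_vline(xintercept = object$trace$iter[
      which.max(object$trace$f1 * object$trace$accepted)],
      linetype = "dotted") +
    ggplot2::labs(x = "Iteration", y = NULL,
                  title = sprintf("Threshold search (T = %.4g, %s mode)",
                                  object$threshold, object$direction_mode)) +
    ggplot2::theme_minimal()
}

#' Plot a classified map
#'
#' @param object A `classified_map` from [classify()].
#' @param ... Unused.
#' @return A ggplot raster of target / other / nodata.
#' @method autoplot classified_map
#' @export
autoplot.classified_map <- function(object, ...) {
  m <- unclass(object)
  attributes(m) <- list(dim = dim(m))
  df <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    class = factor(ifelse(is.na(as.vector(m)), "nodata",
                          ifelse(as.vector(m) == 1, "target", "other")),
                   levels = c("target", "other", "nodata"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(target = "#2d7a2d",
                                          other = "#e8e3d3",
                                          nodata = "grey60")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Per-class mean band trajectories of a scene or composite
#'
#' Averages each band over the labeled sample pixels per class and plots
#' the temporal trajectory — the feature-curve view used to reason about
#' phenological divergence windows.
#'
#' @param series A `composite_series` or [reflectance_stack()].
#' @param samples Labeled samples `(x, y, label)`.
#' @param bands Bands to show (default `c("B6", "B8", "B11")`: red edge,
#'   NIR, SWIR1).
#' @return A ggplot.
#' @export
plot_phenology <- function(series, samples, bands = c("B6", "B8", "B11")) {
  px <- coord_to_pixel(series$geo, samples$x, samples$y)
  ptab <- series_periods(series)
  df <- purrr::map_dfr(bands, function(b) {
    slab <- band_slab(series, b)
    purrr::map_dfr(seq_len(nrow(ptab)), function(p) {
      v <- slab[, , p][cbind(px$row, px$col)]
      tibble::tibble(band = b, mid_doy = ptab$mid_doy[p],
                     label = samples$label, value = v)
    })
  })
  df <- dplyr::summarise(dplyr::group_by(df, .data$band, .data$label,
                                         .data$mid_doy),
                         value = mean(.data$value, na.rm = TRUE),
                         .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_doy, y = .data$value,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "Day of year", y = "Reflectance", colour = NULL) +
    ggplot2::theme_minimal()
}
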