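#' Plot DI versus shear rate by donor group
#'
#' Standard presentation of a deformability cohort: one point per donor and
#' shear condition, with lines connecting group means across shear rates.
#'
#' @param cohort Data frame with columns `group`, `shear_rate_s1` and a DI
#'   column (e.g. from [generate_cohort()] or row-bound [aggregate_donor()]
#'   profiles).
#' @param di_col Name of the DI column.
#' @return A ggplot object.
#' @export
plot_di_profiles <- function(cohort, di_col = "di_mean") {
  means <- cohort |>
    dplyr::group_by(.data$group, .data$shear_rate_s1) |>
    dplyr::summarise(di = mean(.data[[di_col]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$shear_rate_s1,
                               y = .data[[di_col]],
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5, size = 1.5) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$di, group = .data$group),
                       linewidth = 0.9) +
    ggplot2::labs(x = "shear rate (1/s)", y = "mean DI", colour = "group") +
    ggplot2::theme_minimal()
}

#' Display an intensity grid
#'
#' Quick raster display of an [intensity_grid()] (grayscale, origin at the
#' top-left as in image coordinates).
#'
#' @param object An [intensity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_grid <- function(object, ...) {
  v <- as.matrix(object)
  df <- tidyr::expand_grid(y = seq_len(nrow(v)), x = seq_len(ncol(v)))
  df$value <- as.vector(t(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
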