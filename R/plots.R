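# ggplot2 visualisations of the result types.

#' Plot a posterior cluster-location density grid
#'
#' 1D grids are drawn as a column chart over the CCF axis; 2D grids as a
#' heatmap whose red intensity marks a high posterior probability of a
#' cluster, with the leading diagonal indicating clonal structure shared
#' between the two samples.
#'
#' @param density A [density_grid()] tibble.
#' @return A ggplot object.
#' @export
plot_density_grid <- function(density) {
  if ("ccf_2" %in% names(density)) {
    ggplot2::ggplot(density, ggplot2::aes(.data$ccf_1, .data$ccf_2,
                                          fill = .data$density)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "red3") +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "CCF (sample 1)", y = "CCF (sample 2)",
                    fill = "posterior\ndensity") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(density, ggplot2::aes(.data$ccf, .data$density)) +
      ggplot2::geom_col(width = 0.01, fill = "red3") +
      ggplot2::labs(x = "CCF", y = "posterior cluster density") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.dp_fit <- function(object, ...) {
  plot_density_grid(density_grid(object))
}

#' Violin plot of per-sample CCF distributions
#'
#' @param calls A [ccf_calls()] tibble (or any tibble with `sample_id` and
#'   `ccf` columns).
#' @return A ggplot object.
#' @export
plot_ccf_violin <- function(calls) {
  ggplot2::ggplot(ccf_long(calls),
                  ggplot2::aes(.data$sample_id, .data$ccf)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::labs(x = NULL, y = "cancer cell fraction") +
    ggplot2::theme_minimal()
}
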