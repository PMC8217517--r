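# ggplot2 graphics for the main result types.

#' Plot centerlines of a population
#'
#' Head-frame centerlines colored by bend class, with the head axis along
#' +x and the sperm's right toward +y (plotted downward-left convention is
#' avoided: the y axis is flipped so "left" appears on the left).
#'
#' @param pop a `sperm_population` (or any tibble with `specimen_id`,
#'   `centerline` and optionally `beat_class_true`).
#' @param max_specimens cap on the number of curves drawn.
#' @return a ggplot object.
#' @export
plot_waveforms <- function(pop, max_specimens = 60) {
  idx <- seq_len(min(nrow(pop), max_specimens))
  df <- purrr::map2(pop$centerline[idx], pop$specimen_id[idx],
                    function(wf, id) dplyr::mutate(wf, specimen_id = id)) |>
    dplyr::bind_rows()
  if (!is.null(pop$beat_class_true)) {
    df <- dplyr::left_join(
      df,
      tibble(specimen_id = pop$specimen_id[idx],
             class = pop$beat_class_true[idx]),
      by = "specimen_id")
  } else {
    df$class <- "traced"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm / 1000, .data$y_nm / 1000,
                                   group = .data$specimen_id,
                                   color = .data$class)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm, head axis)",
                  y = "y (µm; up = sperm's left)",
                  color = "bend class") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sperm_population <- function(object, ...) plot_waveforms(object, ...)

#' Scree plot of an EFA
#'
#' Eigenvalues of the correlation matrix in decreasing order with the
#' eigenvalue-1 retention line.
#'
#' @param x an `efa_result`.
#' @return a ggplot object.
#' @export
plot_scree <- function(x) {
  df <- tibble(component = seq_along(x$eigenvalues),
               eigenvalue = x$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Loading heatmap of an EFA
#'
#' Varimax-rotated loadings per variable and factor; cells passing the
#' significance cutoff are outlined.
#'
#' @param object an `efa_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.efa_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       color = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}
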