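#' Plot a solved gradient realisation
#'
#' Shows the continuous concentration profile with the per-cell averaged
#' (sensed) concentrations overlaid as steps; source cells are shaded.
#'
#' @param object A `gradient_realization`.
#' @param log_y Plot concentration on a log axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_realization <- function(object, log_y = TRUE, ...) {
  prof <- tibble::tibble(x = object$x, C = object$C)
  cells <- object$cells
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$x, y = .data$C)) +
    ggplot2::annotate("rect", xmin = -object$domain$Ls, xmax = 0,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_segment(
      data = cells,
      ggplot2::aes(x = .data$x_left, xend = .data$x_right,
                   y = .data$C_avg, yend = .data$C_avg),
      colour = "firebrick", linewidth = 0.4
    ) +
    ggplot2::labs(x = "position x (µm)", y = "concentration (arb. units)",
                  title = sprintf("steady-state gradient, decay exponent n = %g",
                                  object$n))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot positional errors from a sweep table
#'
#' Plots the positional error in units of the mean cell diameter against the
#' readout position, coloured by decay exponent, with bootstrap standard
#' errors as error bars. Facets over any extra sweep variable given in
#' `facet`.
#'
#' @param results Sweep table from [run_sweep()] or [run_preset()].
#' @param x Column to map to the x axis (default `x_target_cells`).
#' @param facet Optional column name to facet by.
#' @return A ggplot object.
#' @export
plot_positional_error <- function(results, x = "x_target_cells",
                                  facet = NULL) {
  stopifnot(all(c(x, "sigma_x_cells", "sigma_x_se_cells", "n") %in%
                  names(results)))
  p <- ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data[[x]], y = .data$sigma_x_cells,
                 colour = factor(.data$n), group = factor(.data$n))
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$sigma_x_cells - .data$sigma_x_se_cells,
                   ymax = .data$sigma_x_cells + .data$sigma_x_se_cells),
      size = 0.3
    ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = x, y = "positional error σx / μδ",
                  colour = "decay exponent n")
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(facet)
  }
  p
}

#' @rdname plot_positional_error
#' @param object A `precision_summary` from [positional_error()].
#' @param ... Unused.
#' @export
autoplot.precision_summary <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$x_target_cells, y = .data$sigma_x_cells)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$sigma_x_cells - .data$sigma_x_se_cells,
                   ymax = .data$sigma_x_cells + .data$sigma_x_se_cells)
    ) +
    ggplot2::labs(x = "readout position (cell diameters)",
                  y = "positional error σx / μδ")
}
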