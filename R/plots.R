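#' Plot methods
#'
#' `autoplot()` methods for the result containers: a `pc_series` plots the
#' phase-contrast trace over the cardiac cycle (percent of venc); a
#' `pc_sweep` plots the steady-state deviation against the injected
#' background phase, one line per contrast/interleave/tissue combination.
#' `plot_velocity_map()` shows one cardiac phase of a rendered stack.
#'
#' @param object A `pc_series` or `pc_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot pc_series
#' @export
autoplot.pc_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$pct_venc,
                                       group = .data$pair)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time in cardiac cycle [ms]",
                  y = "phase contrast [%venc]") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot pc_sweep
#' @export
autoplot.pc_sweep <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     mode = paste(.data$interleave, .data$contrast,
                                  .data$t1_ms, .data$t2_ms, sep = "/"))
  ggplot2::ggplot(d, ggplot2::aes(.data$phi_pct_venc,
                                  .data$deviation_pct_venc,
                                  colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected background phase [%venc]",
                  y = "steady-state deviation [%venc]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# traces of all series in a sweep, faceted by mode, coloured by input phase
autoplot_series_sweep <- function(sweep) {
  d <- series_table(sweep) |>
    dplyr::mutate(mode = paste(.data$interleave, .data$contrast, sep = "-"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms,
                                  .data$pct_venc - .data$phi_pct_venc,
                                  colour = factor(.data$phi_pct_venc),
                                  group = interaction(.data$phi_pct_venc,
                                                      .data$pair))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = "time in cardiac cycle [ms]",
                  y = "deviation from input [%venc]",
                  colour = "input [%venc]") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param stack A `pc_stack`.
#' @param phase Cardiac phase index to display.
#' @export
plot_velocity_map <- function(stack, phase = 1) {
  v <- velocity_map(stack)[, , phase]
  d <- tibble::tibble(
    x = rep(seq_len(ncol(v)), each = nrow(v)),
    y = rep(seq_len(nrow(v)), times = ncol(v)),
    velocity = as.vector(v))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$velocity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "v [cm/s]") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
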