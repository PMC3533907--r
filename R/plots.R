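#' @export
autoplot.dspac_fit <- function(object, ...) {
  sc <- object$scatter
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$a)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(
      x = "standardized conservation of residue i",
      y = "neighbor-average conservation",
      title = sprintf("Moran scatterplot (DSPAC = %.3f, n = %d, D = %.1f A)",
                      object$dspac, object$n_points, object$D)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dspac_selection <- function(object, ...) {
  grid <- object$grid[object$grid$eligible & !is.na(object$grid$dspac), ]
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$X, y = .data$dspac,
                               group = .data$D, colour = factor(.data$D))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = object$adopted$X,
                      y = object$adopted$dspac, shape = 1, size = 4,
                      colour = "black") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "percent sequence identity threshold X",
                  y = "DSPAC", colour = "D (A)",
                  title = "DSPAC over the candidate grid") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lmic_mc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cons, y = .data$lmic,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "cons_mean"),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "conservation", y = "LMIC",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
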