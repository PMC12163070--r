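#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stress autocorrelation function
#'
#' Log-log plot of `G(t)`; lags with non-positive `G` are dropped (they
#' are noise about zero in the terminal tail).
#'
#' @param object A [accumulate_g()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot stress_correlation
#' @export
autoplot.stress_correlation <- function(object, ...) {
  d <- object[object$lag > 0 & object$G > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$lag, .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(t / tau[0]),
                  y = expression(G(t) ~ "[" * k[B] * T / sigma^3 * "]"))
}

#' Plot a Green-Kubo viscosity curve
#'
#' @param object A [green_kubo_eta()] result.
#' @param ... Ignored.
#' @return A ggplot with the `eta_inf` estimate marked.
#' @method autoplot viscosity_curve
#' @export
autoplot.viscosity_curve <- function(object, ...) {
  d <- object[object$t > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$eta)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "eta_inf"),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(t / tau[0]),
                  y = expression(eta(t) ~ "[" * k[B] * T ~ tau[0] / sigma^3 * "]"))
}

#' Plot storage and loss moduli
#'
#' @param object A [moduli()] result.
#' @param ... Ignored.
#' @return A ggplot; the crossover frequency, when defined, is marked.
#' @method autoplot dynamic_moduli
#' @export
autoplot.dynamic_moduli <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("Gp", "Gpp"), names_to = "modulus")
  d <- d[d$value > 0, ]
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$omega, .data$value,
                                       colour = .data$modulus)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_discrete(labels = c(Gp = "G'", Gpp = "G''")) +
    ggplot2::labs(x = expression(omega ~ tau[0]),
                  y = expression("modulus [" * k[B] * T / sigma^3 * "]"),
                  colour = NULL)
  wc <- attr(object, "omega_c")
  if (is.finite(wc)) {
    g <- g + ggplot2::geom_vline(xintercept = wc, linetype = 3)
  }
  g
}

#' Plot primitive-path observables along a trajectory
#'
#' Normalized curves (when a reference was given) or absolute `Lpp`, `Z`,
#' `Ne` against rescaled time.
#'
#' @param object A [ppa_timeseries()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ppa_timeseries
#' @export
autoplot.ppa_timeseries <- function(object, ...) {
  rel <- all(c("Lpp_rel", "Z_rel", "Ne_rel") %in% names(object))
  cols <- if (rel) c("Lpp_rel", "Z_rel", "Ne_rel") else c("Lpp", "Z", "Ne")
  xvar <- if (all(is.finite(object$tv_over_L))) "tv_over_L" else "time"
  d <- tidyr::pivot_longer(object, dplyr::all_of(cols),
                           names_to = "observable")
  ggplot2::ggplot(d, ggplot2::aes(.data[[xvar]], .data$value,
                                  colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = if (xvar == "tv_over_L") expression(t * v / L)
                  else expression(t / tau[0]),
                  y = if (rel) "value / passive reference" else "value",
                  colour = NULL)
}

#' Plot a scaling collapse
#'
#' @param object A [rescale_collapse()] result.
#' @param ... Ignored.
#' @return A ggplot of the rescaled curves, annotated with the collapse
#'   score.
#' @method autoplot collapse
#' @export
autoplot.collapse <- function(object, ...) {
  d <- object$curves
  d <- d[d$x > 0 & d$y > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  colour = factor(.data$id))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(t * v / L), y = "rescaled value",
                  colour = "curve",
                  subtitle = paste0("collapse score ",
                                    signif(object$score, 3)))
}
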