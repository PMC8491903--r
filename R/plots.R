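#' Plot a deterministic treatment trajectory
#'
#' Sensitive and resistant compartments over time on a log scale, with the
#' applied dose as a secondary panel caption.
#'
#' @param object A `rescue_trajectory` from [simulate_ode()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rescue_trajectory
#' @export
autoplot.rescue_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("S", "R"),
                              names_to = "compartment", values_to = "cells")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, pmax(.data$cells, 1e-2),
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "cells",
                  title = "Deterministic treatment trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a stochastic dose sweep
#'
#' Simulated cure fraction by dose with its binomial confidence band and
#' the deterministic Poisson-zero-class prediction `exp(-n_rescue(u))`
#' overlaid as a line.
#'
#' @param object A `dose_sweep` from [dose_sweep_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_sweep
#' @export
autoplot.dose_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cure_lo,
                                      ymax = .data$cure_hi), alpha = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cure_fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_cure),
                       linetype = "dashed") +
    ggplot2::labs(x = "dose", y = "cure probability",
                  title = "Cure probability vs dose",
                  subtitle = "points: simulation; dashed: exp(-n_rescue)") +
    ggplot2::theme_minimal()
}

#' Plot a feedback control map
#'
#' The optimal dose as a function of population size and time; outside a
#' boundary layer near the end of treatment the map is time-independent.
#'
#' @param object A `control_map` from [hjb_solve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot control_map
#' @export
autoplot.control_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$t, .data$S, fill = .data$u_opt)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "sensitive cells", fill = "dose",
                  title = "Feedback control map u(S, t)") +
    ggplot2::theme_minimal()
}

#' Plot a relative-cost contour
#'
#' Contours of the cumulative mutation intensity relative to the optimal
#' constant dose, over mutagenicity (alpha) and dose, with the optimal-dose
#' curve overlaid.
#'
#' @param object A `contour_result` from [contour_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contour_result
#' @export
autoplot.contour_result <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$alpha, .data$dose)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$relative_cost),
                          breaks = object$levels, colour = "black") +
    ggplot2::geom_line(data = object$optimal,
                       ggplot2::aes(.data$alpha, .data$u_opt),
                       linetype = "dotdash", inherit.aes = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutation-rate slope alpha", y = "dose",
                  title = "Relative cumulative mutation intensity") +
    ggplot2::theme_minimal()
}
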