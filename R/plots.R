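#' Plot a particle state
#'
#' Draws each agent as a point; colored by heading angle by default, or by
#' SIR compartment if the state carries a `sir` column and `color = "sir"`.
#'
#' @param object a [particle_state()].
#' @param color `"heading"` or `"sir"`.
#' @param size point size.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot particle_state
#' @export
autoplot.particle_state <- function(object, color = c("heading", "sir"),
                                    size = 0.3, ...) {
  color <- match.arg(color)
  L <- state_L(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  if (color == "sir" && "sir" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$sir), size = size) +
      ggplot2::scale_color_manual(
        values = c(S = "grey60", I = "red3", R = "steelblue"), drop = FALSE)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$theta), size = size) +
      ggplot2::scale_color_gradientn(
        colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
        limits = c(-pi, pi), name = "heading")
  }
  p + ggplot2::coord_fixed(xlim = c(0, L), ylim = c(0, L), expand = FALSE) +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed density grid with the infected overlay
#'
#' @param object a [render_density_grid()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  nb <- object$n_bins
  h <- object$L / nb
  centers <- (seq_len(nb) - 0.5) * h
  # matrices are indexed [x-bin, y-bin]; as.vector runs x fastest
  grid <- tidyr::expand_grid(yc = centers, xc = centers)
  grid$density <- as.vector(object$total_smooth)
  grid$infected <- as.vector(object$infected)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$xc, y = .data$yc)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 name = "density")
  inf <- dplyr::filter(grid, .data$infected > 0)
  if (nrow(inf) > 0) {
    p <- p + ggplot2::geom_point(
      data = inf, ggplot2::aes(color = .data$infected), size = 0.8) +
      ggplot2::scale_color_gradient(low = "mistyrose", high = "red3",
                                    name = "infected")
  }
  p + ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot the time course of an outbreak
#'
#' @param object a [run_outbreak()] result.
#' @param ... unused.
#' @return A ggplot object showing the S, I, R fractions over time.
#' @method autoplot swarm_outbreak
#' @export
autoplot.swarm_outbreak <- function(object, ...) {
  n <- sum(object$series[1, c("n_s", "n_i", "n_r")])
  long <- object$series |>
    dplyr::mutate(S = .data$n_s / n, I = .data$n_i / n, R = .data$n_r / n) |>
    tidyr::pivot_longer(c("S", "I", "R"), names_to = "compartment",
                        values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$fraction,
                                     color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(S = "grey40", I = "red3", R = "steelblue")) +
    ggplot2::labs(x = "time", y = "population fraction") +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep of outbreak effectiveness
#'
#' Mean final recovered fraction against the sweep axis, with one-standard-
#' deviation error bars, on a log-scaled axis.
#'
#' @param object a [theta_sweep()] or [tinf_sweep()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot swarm_sweep
#' @export
autoplot.swarm_sweep <- function(object, ...) {
  axis <- attr(object, "axis")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axis]],
                                       y = .data$mean_rho_r)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_rho_r - .data$sd_rho_r),
      ymax = pmin(1, .data$mean_rho_r + .data$sd_rho_r)), width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (axis == "theta") expression(Theta) else
      expression(T[inf]), y = expression(rho[R](infinity))) +
    ggplot2::theme_minimal()
}
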