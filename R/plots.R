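#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_path
#'   geom_tile labs scale_y_log10 facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an empirical frequency response
#'
#' Magnitude (dB) and unwrapped phase (degrees) of the FRF over its band.
#'
#' @param object An [empirical_frf()] estimate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frf_estimate <- function(object, ...) {
  ph <- Arg(object$response)
  ph <- ph - 2 * pi * cumsum(c(0, diff(ph) > pi)) +
    2 * pi * cumsum(c(0, diff(ph) < -pi))
  df <- tibble(
    freq = rep(object$freq, 2),
    value = c(20 * log10(Mod(object$response)), ph * 180 / pi),
    panel = rep(c("magnitude (dB)", "phase (deg)"), each = nrow(object))
  )
  ggplot(df, aes(x = .data$freq, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "frequency (Hz)", y = NULL,
         title = "Empirical frequency response") +
    theme_minimal()
}

#' Plot a Hopf stability contour
#'
#' The (alpha, beta) boundary in the positive quadrant, colored by the
#' crossing frequency omega.
#'
#' @param object A [hopf_contour()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_contour <- function(object, ...) {
  quad <- object[object$alpha > 0 & object$beta > 0, ]
  ggplot(quad, aes(x = .data$alpha, y = .data$beta, color = .data$omega)) +
    geom_path() +
    labs(x = expression(alpha), y = expression(beta),
         title = "Hopf stability boundary") +
    theme_minimal()
}

#' Plot a stability region map
#'
#' Per-cell mean-field verdicts for the solo and group delay distributions.
#'
#' @param object A [region_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_map <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("verdict_solo", "verdict_group"),
                            names_to = "condition", values_to = "verdict")
  ggplot(df, aes(x = .data$alpha, y = .data$beta, fill = .data$verdict)) +
    geom_tile() +
    facet_wrap(~condition) +
    labs(x = expression(alpha), y = expression(beta),
         title = "Mean-field stability map") +
    theme_minimal()
}

#' Plot swarm agent paths
#'
#' Planar trajectories of all agents, plus the swarm-center path.
#'
#' @param object A [simulate_swarm()] trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swarm_trajectory <- function(object, ...) {
  df <- tidy(object)
  ctr <- swarm_center(object)
  ggplot(df, aes(x = .data$x, y = .data$y, group = .data$agent)) +
    geom_path(alpha = 0.4) +
    geom_path(data = ctr, aes(x = .data$cx, y = .data$cy, group = 1),
              color = "red", linewidth = 1) +
    labs(x = "x", y = "y", title = "Swarm trajectories (center in red)") +
    theme_minimal()
}

#' Plot a fitted delay distribution over its sample
#'
#' Histogram of the identified delays with the fitted shifted-gamma density.
#'
#' @param object A [fit_shifted_gamma()] result.
#' @param bins Histogram bins (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shifted_gamma_fit <- function(object, bins = 20, ...) {
  df <- tibble(delay = object$delays)
  grid <- tibble(
    delay = seq(min(df$delay), max(df$delay), length.out = 200)
  )
  grid$density <- gamma_density(object$dist, grid$delay)
  ggplot(df, aes(x = .data$delay)) +
    ggplot2::geom_histogram(aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", color = "grey40") +
    geom_line(data = grid, aes(y = .data$density), color = "red") +
    labs(x = "delay", y = "density", title = "Fitted delay distribution") +
    theme_minimal()
}
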