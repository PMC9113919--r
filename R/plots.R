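# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline geom_contour facet_wrap labs scale_fill_viridis_c
#'   geom_hline theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.spectral_envelope <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$log2_sf, .data$log2_tf, fill = .data$mass)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "log2 spatial frequency (c/deg)", y = "log2 temporal frequency (Hz)",
         fill = "mass", title = attr(object, "id")) +
    theme_minimal()
}

#' @export
autoplot.posterior_sequence <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$log2_v, .data$posterior, colour = factor(.data$omega))) +
    geom_line() +
    labs(x = "log2 speed (deg/s)", y = "posterior density", colour = "window") +
    theme_minimal()
}

#' @export
autoplot.quadric_fit <- function(object, n = 60, ...) {
  d <- object$data
  gx <- seq(min(d$x), max(d$x), length.out = n)
  gt <- seq(min(d$t), max(d$t), length.out = n)
  q <- object$coefficients
  surf <- tidyr::expand_grid(x = gx, t = gt) |>
    mutate(z = q[1] + q[2] * .data$x + q[3] * .data$t + q[4] * .data$x^2 +
             q[5] * .data$x * .data$t + q[6] * .data$t^2)
  ggplot(surf, aes(.data$x, .data$t)) +
    geom_contour(aes(z = .data$z, colour = ggplot2::after_stat(level))) +
    geom_point(data = d, aes(size = .data$amplitude), alpha = 0.7) +
    labs(x = "log2 sf", y = "log2 tf", size = "amplitude", colour = "fit") +
    theme_minimal()
}

#' Plot across-trial SD against mean window velocity
#'
#' Displays the square-root-of-mean reference line against which the
#' `sigma_d` deviation is defined.
#'
#' @param stats Output of [window_stats()].
#' @return A ggplot.
#' @export
plot_sigma_mu <- function(stats) {
  ref <- tibble(mu = seq(0, max(stats$mu) * 1.05, length.out = 100)) |>
    mutate(sigma = sqrt(.data$mu))
  ggplot(stats, aes(.data$mu, .data$sigma)) +
    geom_line(data = ref, linetype = 2) +
    geom_point(aes(colour = .data$window)) +
    labs(x = "mean eye velocity (deg/s)", y = "across-trial SD (deg/s)") +
    theme_minimal()
}

#' Plot the interaction kernel over frequency displacement
#'
#' @param params An [interaction_params()].
#' @param half_width Half-width of the displacement box (octaves).
#' @param n Nodes per side.
#' @return A ggplot.
#' @export
plot_interaction_kernel <- function(params = interaction_params(),
                                    half_width = 3, n = 101) {
  d <- interaction_kernel(params)
  grid <- tidyr::expand_grid(dx = seq(-half_width, half_width, length.out = n),
                             dt = seq(-half_width, half_width, length.out = n)) |>
    mutate(value = d(.data$dx, .data$dt))
  ggplot(grid, aes(.data$dx, .data$dt, fill = .data$value)) +
    geom_raster() +
    ggplot2::scale_fill_gradient2() +
    labs(x = "log2 sf displacement", y = "log2 tf displacement",
         fill = "d") +
    theme_minimal()
}

#' Plot nonlinearity ratios over windows
#'
#' @param rnl_table Row-bound [r_nl()] outputs with a `pattern` column.
#' @return A ggplot.
#' @export
plot_rnl <- function(rnl_table) {
  ggplot(rnl_table, aes(.data$window, .data$r_nl, group = .data$pattern,
                        colour = .data$pattern)) +
    geom_hline(yintercept = 1, linetype = 2) +
    geom_line() + geom_point() +
    labs(x = "time window (ms)", y = expression(R[NL])) +
    theme_minimal()
}
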