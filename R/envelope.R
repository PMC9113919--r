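# Spectral envelopes: discretized motion-energy distributions over the
# (log2 sf, log2 tf) plane. The envelope is the common currency between
# stimulus descriptions and the channel model.

#' Build a rectangular log-frequency lattice
#'
#' @param x_range,t_range Ranges in log2 cycles/deg and log2 Hz.
#' @param n Nodes per side (the lattice is `n x n`).
#' @return List with axes `x`, `t` and class `envelope_grid`.
#' @export
envelope_grid <- function(x_range, t_range, n = 64) {
  stopifnot(length(x_range) == 2, length(t_range) == 2, n >= 4)
  structure(list(x = seq(x_range[1], x_range[2], length.out = n),
                 t = seq(t_range[1], t_range[2], length.out = n)),
            class = "envelope_grid")
}

default_grid <- function(x0, t0, half_width = 3, n = 64) {
  envelope_grid(x0 + c(-1, 1) * half_width, t0 + c(-1, 1) * half_width, n)
}

new_envelope <- function(grid, mass, spec, type, point = NULL) {
  nodes <- expand.grid(log2_sf = grid$x, log2_tf = grid$t,
                       KEEP.OUT.ATTRS = FALSE)
  env <- tibble(log2_sf = nodes$log2_sf, log2_tf = nodes$log2_tf,
                mass = as.vector(mass))
  structure(env,
            class = c("spectral_envelope", class(env)),
            grid = grid, id = spec$id, stimulus_type = type,
            total_contrast = spec$contrast, point = point)
}

#' Motion-cloud spectral envelope
#'
#' The motion-cloud generative model draws Gabor element characteristics
#' from log-normal distributions of spatial frequency and speed (and a Von
#' Mises distribution of orientation, marginalized out here: the decoding
#' model is two-dimensional in frequency). In log2 coordinates the energy
#' density is therefore a product of two Gaussians, in `x = log2 sf` with
#' FWHM `b_sf` octaves and in `log2 v` with FWHM `b_v` octaves, sheared to
#' the (log2 sf, log2 tf) plane through `log2 tf = log2 sf + log2 v`. The
#' result is the oblique ellipse of motion energy oriented along the
#' stimulus's iso-velocity line.
#'
#' @param spec One component row from [stimulus_catalog()] with
#'   `stimulus_type == "MC"`.
#' @param grid An [envelope_grid()]; default spans +/- 3 octaves around the
#'   component centre with 64 x 64 nodes.
#' @param n Nodes per side for the default grid.
#' @return A `spectral_envelope` tibble (`log2_sf`, `log2_tf`, `mass`), mass
#'   normalized to sum to 1. A warning reports the truncated fraction when
#'   the grid clips more than 1% of the analytic mass.
#' @examples
#' c1 <- stimulus_catalog()$components[1, ]
#' env <- mc_envelope(c1)
#' sum(env$mass)
#' @export
mc_envelope <- function(spec, grid = NULL, n = 64) {
  stopifnot(nrow(spec) == 1)
  if (spec$stimulus_type != "MC") {
    abort(sprintf("mc_envelope() needs an MC component; '%s' is %s.",
                  spec$id, spec$stimulus_type))
  }
  x0 <- log2(spec$sf0); t0 <- log2(spec$tf0); v0 <- t0 - x0
  if (is.null(grid)) grid <- default_grid(x0, t0, n = n)
  s_sf <- fwhm_to_sigma(spec$b_sf)
  s_v <- fwhm_to_sigma(spec$b_v)
  xg <- grid$x; tg <- grid$t
  dens <- outer(xg, tg, function(x, t) {
    dnorm(x, x0, s_sf) * dnorm(t - x, v0, s_v)
  })
  dA <- diff(xg[1:2]) * diff(tg[1:2])
  covered <- sum(dens) * dA
  if (covered < 0.99) {
    warn(sprintf("Envelope grid for '%s' truncates %.1f%% of the analytic mass.",
                 spec$id, 100 * (1 - covered)))
  }
  new_envelope(grid, dens / sum(dens), spec, "MC")
}

#' Drifting-grating spectral envelope
#'
#' A drifting grating is a single point in the frequency plane (zero-width
#' distribution parameters), so all mass sits on the lattice node nearest
#' `(log2 sf0, log2 tf0)`. The exact point is kept in the `point` attribute
#' so the channel model can evaluate tuning functions at the true
#' coordinates instead of the snapped node.
#'
#' @inheritParams mc_envelope
#' @return A `spectral_envelope` with a single nonzero node.
#' @export
dg_envelope <- function(spec, grid = NULL, n = 64) {
  stopifnot(nrow(spec) == 1)
  if (spec$stimulus_type != "DG") {
    abort(sprintf("dg_envelope() needs a DG component; '%s' is %s.",
                  spec$id, spec$stimulus_type))
  }
  x0 <- log2(spec$sf0); t0 <- log2(spec$tf0)
  if (is.null(grid)) grid <- default_grid(x0, t0, n = n)
  if (x0 < min(grid$x) || x0 > max(grid$x) || t0 < min(grid$t) || t0 > max(grid$t)) {
    abort(sprintf("Component '%s' at (%.3f, %.3f) log2 units lies outside the grid.",
                  spec$id, x0, t0))
  }
  mass <- matrix(0, length(grid$x), length(grid$t))
  mass[which.min(abs(grid$x - x0)), which.min(abs(grid$t - t0))] <- 1
  new_envelope(grid, mass, spec, "DG", point = c(x = x0, t = t0))
}

component_envelope <- function(spec, grid = NULL, n = 64) {
  if (spec$stimulus_type == "MC") mc_envelope(spec, grid, n) else dg_envelope(spec, grid, n)
}

#' Pattern spectral envelope
#'
#' Patterns superimpose 2-3 components; in the decoding model the pattern
#' drive is the *average* of the component drives, so the pattern envelope
#' is the node-wise arithmetic mean of the component envelopes evaluated on
#' a common lattice (the union box of the component boxes). Components must
#' all be of one stimulus type; mixing MC and DG components is not a study
#' condition and is rejected.
#'
#' @param pattern One pattern row from [stimulus_catalog()].
#' @param components The component tibble of the same catalog.
#' @param grid Common [envelope_grid()]; default is the union box spanning
#'   +/- 3 octaves around every member component.
#' @param n Nodes per side for the default grid.
#' @return A `spectral_envelope`; mass sums to 1 by linearity.
#' @export
pattern_envelope <- function(pattern, components, grid = NULL, n = 64) {
  stopifnot(nrow(pattern) == 1)
  ids <- pattern$component_ids[[1]]
  members <- components[match(ids, components$id), ]
  if (anyNA(members$id)) {
    abort(sprintf("Pattern '%s' references unknown components.", pattern$id))
  }
  if (length(unique(members$stimulus_type)) != 1) {
    abort("Mixed MC/DG components in one pattern are not supported.")
  }
  if (is.null(grid)) {
    xs <- log2(members$sf0); ts <- log2(members$tf0)
    grid <- envelope_grid(range(xs) + c(-3, 3), range(ts) + c(-3, 3), n)
  }
  envs <- map(seq_len(nrow(members)),
              ~ component_envelope(members[.x, ], grid = grid))
  mass <- Reduce(`+`, map(envs, ~ .x$mass)) / length(envs)
  out <- new_envelope(grid, mass, pattern, members$stimulus_type[1])
  attr(out, "member_points") <- map(envs, ~ attr(.x, "point"))
  out
}

#' Marginal of a spectral envelope along one axis
#'
#' @param env A `spectral_envelope`.
#' @param axis `"log2_sf"` or `"log2_tf"`.
#' @return Tibble with the axis values and summed `mass`.
#' @export
envelope_marginal <- function(env, axis = c("log2_sf", "log2_tf")) {
  axis <- match.arg(axis)
  env |>
    as_tibble() |>
    group_by(value = .data[[axis]]) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    arrange(.data$value)
}

#' FWHM of an envelope marginal, in octaves
#'
#' Measures the full width at half of the marginal's peak by linear
#' interpolation between lattice nodes.
#'
#' @inheritParams envelope_marginal
#' @return Width in log2-frequency units (octaves).
#' @examples
#' env <- mc_envelope(stimulus_catalog()$components[1, ])
#' envelope_fwhm(env, "log2_sf")  # ~ 1 octave
#' @export
envelope_fwhm <- function(env, axis = c("log2_sf", "log2_tf")) {
  m <- envelope_marginal(env, axis)
  sampled_fwhm(m$value, m$mass)
}
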