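# The spatiotemporal channel bank: bivariate Gaussian channels tiling the
# log2 frequency plane, with weights from a quadratic log-weight surface.

#' Channel bank specification
#'
#' Channels are bivariate normal tuning functions over (log2 sf, log2 tf)
#' with common covariance `[[sx^2, rho sx st], [rho sx st, st^2]]`; the
#' correlation `rho` concentrates each channel along its iso-velocity line
#' (rho = 1 would be a pure speed channel, rho = 0 fully separable). The
#' default bank tiles a regular lattice of 19 log2-sf values by 38 preferred
#' speeds, homogeneously covering 1-512 deg/s, i.e. 722 channels.
#'
#' @param n_sf,n_speed Lattice dimensions (channels = n_sf * n_speed).
#' @param speed_range Preferred-speed coverage in deg/s.
#' @param sf_range Preferred spatial-frequency coverage in cyc/deg.
#' @param sigma_x,sigma_t Channel SDs in log2-frequency units (octaves).
#' @param rho Channel correlation coefficient.
#' @return List of class `bank_spec`.
#' @export
bank_spec <- function(n_sf = 19, n_speed = 38, speed_range = c(1, 512),
                      sf_range = c(0.0625, 4), sigma_x = 0.5, sigma_t = 0.5,
                      rho = 0.6) {
  if (rho <= -1 || rho >= 1) abort("rho must lie in (-1, 1).")
  if (sigma_x <= 0 || sigma_t <= 0) abort("Channel SDs must be positive.")
  structure(list(n_sf = n_sf, n_speed = n_speed, speed_range = speed_range,
                 sf_range = sf_range, sigma_x = sigma_x, sigma_t = sigma_t,
                 rho = rho),
            class = "bank_spec")
}

#' Default channel-weight polynomial coefficients
#'
#' Coefficients `b0..b5` of the quadratic log-weight surface
#' `log w = b0 + b1 x + b2 t + b3 x^2 + b4 x t + b5 t^2` over
#' `(x, t) = (log2 sf, log2 tf)`. With these reference values the weights
#' peak for channels centred near 0.21 cyc/deg, and fall off for channels
#' beyond the window of visibility.
#'
#' @return Named numeric vector `b0..b5`.
#' @export
default_weight_coefficients <- function() {
  setNames(c(-23.88, -3.63, 1.95, -0.72, 0.61, -0.45), paste0("b", 0:5))
}

#' Evaluate the weight polynomial
#'
#' @param x,t Log2 spatial and temporal frequency.
#' @param b Coefficients `b0..b5`.
#' @return Polynomial values (log-weight units).
#' @export
weight_polynomial <- function(x, t, b = default_weight_coefficients()) {
  b[1] + b[2] * x + b[3] * t + b[4] * x^2 + b[5] * x * t + b[6] * t^2
}

#' Location of the weight-polynomial maximum
#'
#' Solves the stationary point of the quadratic log-weight surface
#' analytically and returns it in frequency units. The Hessian must be
#' negative definite for a maximum to exist.
#'
#' @param b Coefficients `b0..b5`.
#' @return Tibble with `sf` (cyc/deg), `tf` (Hz) and the log2 coordinates.
#' @export
weight_peak <- function(b = default_weight_coefficients()) {
  H <- matrix(c(2 * b[4], b[5], b[5], 2 * b[6]), 2, 2)
  if (!(H[1, 1] < 0 && det(H) > 0)) abort("Weight surface has no maximum.")
  st <- solve(H, -c(b[2], b[3]))
  tibble(sf = 2^st[1], tf = 2^st[2], log2_sf = st[1], log2_tf = st[2])
}

#' Build the channel bank
#'
#' Lays a regular lattice over (log2 sf, log2 preferred speed) - i.e. a
#' homogeneous rectangle of preferred speeds, sheared into (log2 sf,
#' log2 tf) - and attaches each channel's weight. The quadratic surface is
#' a log-weight: weights are `exp` of the polynomial, normalized to peak at
#' 1 over the bank, so all weights are positive and the overall response
#' scale is carried by the gain parameter.
#'
#' @param spec A [bank_spec()].
#' @param b Weight-polynomial coefficients `b0..b5`.
#' @return Tibble of class `channel_bank`: one row per channel with `x`
#'   (log2 sf), `t` (log2 tf), `v` (preferred speed, deg/s), `log2_v`,
#'   `weight`; bank parameters kept as attributes.
#' @examples
#' bank <- build_bank()
#' nrow(bank) # 722
#' @export
build_bank <- function(spec = bank_spec(), b = default_weight_coefficients()) {
  xs <- seq(log2(spec$sf_range[1]), log2(spec$sf_range[2]),
            length.out = spec$n_sf)
  vs <- seq(log2(spec$speed_range[1]), log2(spec$speed_range[2]),
            length.out = spec$n_speed)
  grid <- expand.grid(x = xs, log2_v = vs, KEEP.OUT.ATTRS = FALSE)
  bank <- tibble(x = grid$x, log2_v = grid$log2_v,
                 t = grid$x + grid$log2_v, v = 2^grid$log2_v)
  lw <- weight_polynomial(bank$x, bank$t, b)
  bank$weight <- exp(lw - max(lw))
  if (any(bank$v < spec$speed_range[1] - 1e-9 |
            bank$v > spec$speed_range[2] + 1e-9)) {
    abort("Bank lattice produced preferred speeds outside speed_range.")
  }
  structure(bank, class = c("channel_bank", class(bank)), spec = spec,
            weights_b = b)
}

# unnormalized bivariate normal channel density evaluated at points
# (rows of cbind(x, t)) for channel centres (cx, ct); returns the proper
# density (integrates to 1 over the plane)
channel_density <- function(px, pt, cx, ct, spec) {
  sx <- spec$sigma_x; st <- spec$sigma_t; rho <- spec$rho
  det2 <- sx^2 * st^2 * (1 - rho^2)
  dx <- outer(cx, px, function(a, b) b - a)
  dt <- outer(ct, pt, function(a, b) b - a)
  qf <- (dx^2 / sx^2 - 2 * rho * dx * dt / (sx * st) + dt^2 / st^2) / (1 - rho^2)
  exp(-qf / 2) / (2 * pi * sqrt(det2))
}

#' Feedforward channel responses to a stimulus
#'
#' Implements the drive `m_i = g^2 w_i <phi_i, stimulus> contrast`. For a
#' drifting grating the channel tuning function is evaluated at the exact
#' stimulus coordinates; for a motion cloud it is integrated against the
#' discretized spectral envelope (a weighted average over the grating
#' micro-components the envelope stands for).
#'
#' @param bank A `channel_bank`.
#' @param envelope A `spectral_envelope` (mass summing to 1), or for the
#'   point path a `spectral_envelope` carrying an exact `point` attribute.
#' @param g Gain multiplier (participant parameter).
#' @param contrast RMS contrast in (0, 1]; defaults to the envelope's.
#' @return Numeric vector `m` of length `nrow(bank)`.
#' @export
channel_response <- function(bank, envelope, g = 1, contrast = NULL) {
  spec <- attr(bank, "spec")
  if (is.null(contrast)) contrast <- attr(envelope, "total_contrast")
  pt <- attr(envelope, "point")
  if (!is.null(pt)) {
    phi <- channel_density(pt["x"], pt["t"], bank$x, bank$t, spec)[, 1]
  } else {
    if (abs(sum(envelope$mass) - 1) > 1e-6) {
      abort("Envelope mass must be normalized to 1.")
    }
    phi <- envelope_phi(bank, envelope, spec)
  }
  g^2 * bank$weight * phi * contrast
}

# <phi_i, envelope> for all channels, blocked over envelope nodes to bound
# memory on dense grids
envelope_phi <- function(bank, envelope, spec, block = 16384L) {
  nz <- which(envelope$mass > 0)
  out <- numeric(nrow(bank))
  for (start in seq(1, length(nz), by = block)) {
    idx <- nz[start:min(start + block - 1, length(nz))]
    out <- out + as.vector(
      channel_density(envelope$log2_sf[idx], envelope$log2_tf[idx],
                      bank$x, bank$t, spec) %*% envelope$mass[idx])
  }
  out
}

#' Precompute envelope overlaps for a set of stimuli
#'
#' The envelope integral `<phi_i, s>` does not depend on the gain or prior
#' parameters, so model fitting precomputes it once per stimulus.
#'
#' @param bank A `channel_bank`.
#' @param envelopes Named list of `spectral_envelope`s.
#' @return Matrix channels x stimuli of overlap values (already including
#'   weights and contrast; multiply by `g^2` to get `m`).
#' @export
stimulus_drive <- function(bank, envelopes) {
  out <- vapply(envelopes, function(e) channel_response(bank, e, g = 1),
                numeric(nrow(bank)))
  colnames(out) <- names(envelopes)
  out
}
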