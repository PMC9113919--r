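# Dynamic probabilistic decoding: channel interactions in speed-scale
# coordinates, population speed likelihood, and the recursive posterior
# over log2 speed.

#' Participant-level model parameters
#'
#' @param g Channel gain multiplier (unitless, > 0). The likelihood drive
#'   scales with `g^2`, so `g` sets how much evidence each 50-ms window
#'   contributes relative to the prior.
#' @param mu_prior Mean of the initial log-normal speed prior, in natural-log
#'   speed units (`mu_prior = 2.51` puts the prior near 12.3 deg/s).
#' @param sigma_prior SD of the prior in natural-log speed units.
#' @return List of class `participant_params`.
#' @export
participant_params <- function(g = 2, mu_prior = 2.51, sigma_prior = 0.86) {
  if (g <= 0 || sigma_prior <= 0) abort("g and sigma_prior must be positive.")
  structure(list(g = g, mu_prior = mu_prior, sigma_prior = sigma_prior),
            class = "participant_params")
}

#' Interaction kernel parameters
#'
#' The channel-interaction kernel is a difference of two peak-normalized
#' bivariate Gaussians over log2-frequency displacement: an excitatory lobe
#' elongated along the speed (iso-velocity) diagonal and an inhibitory lobe
#' elongated along the orthogonal scale diagonal. `theta_rot` orients the
#' lobe axes on the diagonals (3*pi/4 by default); the inhibitory SDs are
#' assigned to the two axes in the opposite order to the excitatory SDs,
#' which is what produces the crossed excitation-along-speed /
#' inhibition-along-scale structure.
#'
#' @param alpha Interaction magnitude.
#' @param sigma_e1,sigma_e2 Excitatory SDs (octaves) along the first
#'   (scale-diagonal) and second (speed-diagonal) kernel axes.
#' @param sigma_i1,sigma_i2 Inhibitory SDs (octaves); `sigma_i1` narrow
#'   along the speed diagonal, `sigma_i2` broad along the scale diagonal.
#' @param theta_rot Rotation of the kernel axes (radians).
#' @return List of class `interaction_params`.
#' @export
interaction_params <- function(alpha = 2.16, sigma_e1 = 0.2542,
                               sigma_e2 = 0.7718, sigma_i1 = 0.2501,
                               sigma_i2 = 0.7711, theta_rot = 3 * pi / 4) {
  if (any(c(sigma_e1, sigma_e2, sigma_i1, sigma_i2) <= 0)) {
    abort("Kernel SDs must be positive.")
  }
  structure(list(alpha = alpha, sigma_e1 = sigma_e1, sigma_e2 = sigma_e2,
                 sigma_i1 = sigma_i1, sigma_i2 = sigma_i2,
                 theta_rot = theta_rot),
            class = "interaction_params")
}

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

kernel_covs <- function(params) {
  R <- rot2(params$theta_rot)
  Se <- R %*% diag(c(params$sigma_e1^2, params$sigma_e2^2)) %*% t(R)
  # inhibition: SDs assigned to the axes in swapped order (crossed lobes)
  Si <- R %*% diag(c(params$sigma_i2^2, params$sigma_i1^2)) %*% t(R)
  list(Se = Se, Si = Si)
}

#' Interaction kernel over frequency displacement
#'
#' Returns `d(dx, dt) = alpha * (exc(dx, dt) - inh(dx, dt))` where both
#' lobes are zero-mean bivariate Gaussians normalized to 1 at the origin,
#' so `d(0, 0) = 0` and `d` is even. With the default parameters the kernel
#' is positive for displacements along the iso-velocity diagonal
#' (excitatory pooling along speed) and negative along the scale diagonal
#' (inhibition between channels of equal speed-orthogonal offset).
#'
#' @param params An [interaction_params()].
#' @return A vectorized function `d(dx, dt)` of log2-frequency displacement.
#' @examples
#' d <- interaction_kernel(interaction_params())
#' d(0, 0)
#' d(-3 / sqrt(2), 3 / sqrt(2)) # 3 octaves along the scale diagonal: < 0
#' @export
interaction_kernel <- function(params) {
  cv <- kernel_covs(params)
  Pe <- solve(cv$Se); Pi <- solve(cv$Si)
  a <- params$alpha
  function(dx, dt) {
    qe <- Pe[1, 1] * dx^2 + 2 * Pe[1, 2] * dx * dt + Pe[2, 2] * dt^2
    qi <- Pi[1, 1] * dx^2 + 2 * Pi[1, 2] * dx * dt + Pi[2, 2] * dt^2
    a * (exp(-qe / 2) - exp(-qi / 2))
  }
}

#' Pairwise interaction matrix for a channel bank
#'
#' @param bank A `channel_bank`.
#' @param params An [interaction_params()].
#' @return Symmetric matrix `D` with `D[i, j] = d(x_j - x_i, t_j - t_i)` and
#'   zero diagonal.
#' @export
interaction_matrix <- function(bank, params) {
  d <- interaction_kernel(params)
  dx <- outer(bank$x, bank$x, function(a, b) b - a)
  dt <- outer(bank$t, bank$t, function(a, b) b - a)
  d(dx, dt)
}

#' Apply network interactions to the feedforward drive
#'
#' Each channel's activity is increased or decreased by the kernel-weighted
#' sum of the activity of the other channels, `I_i = sum_j m_j d_ij`. In the
#' default mode the post-interaction activity is `n_i = max(0, m_i (1 + I_i))`,
#' which reduces exactly to `n = m` when the kernel vanishes; `mode =
#' "literal"` uses the bare product `n_i = m_i I_i`, and `mode = "off"`
#' bypasses interactions.
#'
#' @param m Feedforward responses (vector).
#' @param D Interaction matrix from [interaction_matrix()], or `NULL` with
#'   `mode = "off"`.
#' @param mode `"default"`, `"literal"` or `"off"`.
#' @return Vector `n` of network activities.
#' @export
apply_interactions <- function(m, D = NULL, mode = c("default", "literal", "off")) {
  mode <- match.arg(mode)
  if (mode == "off") return(m)
  if (is.null(D)) abort("Interaction matrix required unless mode = 'off'.")
  I <- as.vector(D %*% m)
  switch(mode,
         default = pmax(0, m * (1 + I)),
         literal = m * I)
}

#' Log2-speed decoding grid
#'
#' @param range Log2-speed range (default 0.25 to 1024 deg/s).
#' @param n Number of grid points.
#' @return Numeric vector of log2 speeds with attribute `dv` (spacing).
#' @export
speed_grid <- function(range = c(-2, 10), n = 512) {
  g <- seq(range[1], range[2], length.out = n)
  attr(g, "dv") <- g[2] - g[1]
  g
}

#' Per-channel speed tuning on the decoding grid
#'
#' Each channel's speed tuning is the Gaussian cross-section of its
#' receptive field along the iso-scale direction: unit peak at the channel's
#' preferred log2 speed with variance `sigma^2 (1 - rho)` (requires
#' `sigma_x == sigma_t`).
#'
#' @param bank A `channel_bank`.
#' @param grid A [speed_grid()].
#' @return Matrix `log psi`, channels x grid points (values <= 0).
#' @export
speed_logpsi <- function(bank, grid) {
  spec <- attr(bank, "spec")
  if (abs(spec$sigma_x - spec$sigma_t) > 1e-12) {
    abort("Speed tuning assumes sigma_x == sigma_t.")
  }
  vv <- spec$sigma_x^2 * (1 - spec$rho)
  -outer(log2(bank$v), as.numeric(grid), `-`)^2 / (2 * vv)
}

#' Population log-likelihood of speed
#'
#' @param n Network activities (vector).
#' @param logpsi Matrix from [speed_logpsi()].
#' @return Log-likelihood over the grid (up to an additive constant).
#' @export
speed_loglik <- function(n, logpsi) {
  as.vector(crossprod(logpsi, n))
}

#' One recursive Bayesian update of the speed posterior
#'
#' Pointwise product of the previous posterior with the (max-normalized)
#' exponentiated log-likelihood, renormalized to integrate to 1 on the grid.
#'
#' @param prior Density over the grid (integrates to 1).
#' @param loglik Log-likelihood over the grid.
#' @param grid A [speed_grid()].
#' @return Posterior density over the grid.
#' @export
posterior_update <- function(prior, loglik, grid) {
  if (abs(sum(prior) * attr(grid, "dv") - 1) > 1e-6) {
    abort("Prior must integrate to 1 on the grid.")
  }
  post <- prior * exp(loglik - max(loglik))
  z <- sum(post) * attr(grid, "dv")
  if (!is.finite(z) || z <= 0) {
    abort(sprintf("Posterior underflow: normalizer = %g (likelihood too peaked or disjoint from prior support).", z))
  }
  post / z
}

prior_density <- function(participant, grid) {
  mu <- participant$mu_prior / log(2)
  s <- participant$sigma_prior / log(2)
  p <- dnorm(as.numeric(grid), mu, s)
  p / (sum(p) * attr(grid, "dv"))
}

#' Analysis windows of the decoding recursion
#'
#' The first model window (omega = 0, the prior stage) is 101-150 ms; the
#' recursion is fitted over the following three 50-ms windows.
#'
#' @return Tibble `omega`, `window`.
#' @export
model_windows <- function() {
  tibble(omega = 0:3, window = c("101-150", "151-200", "201-250", "251-300"))
}

#' Run the decoding recursion across time windows
#'
#' Computes the feedforward drive (held constant across windows; the
#' temporal dynamics come entirely from the posterior recursion), applies
#' interactions, and updates the posterior window by window starting from
#' the log-normal prior at omega = 0.
#'
#' @param drive Unit-gain feedforward drive for one stimulus (a column of
#'   [stimulus_drive()], i.e. `w_i <phi_i, s> contrast`), or a
#'   `spectral_envelope` (converted internally).
#' @param bank A `channel_bank`.
#' @param participant A [participant_params()].
#' @param interactions An [interaction_params()], a precomputed interaction
#'   matrix, or `NULL` for no interactions.
#' @param grid A [speed_grid()].
#' @param n_windows Number of update windows after the prior stage.
#' @param mode Interaction mode, see [apply_interactions()].
#' @param logpsi Optional precomputed [speed_logpsi()] matrix.
#' @return A `posterior_sequence`: tibble `omega`, `log2_v`, `posterior`
#'   with the density matrix, grid and network state in attributes.
#' @examples
#' cat15 <- stimulus_catalog("DG")
#' bank <- build_bank()
#' drv <- channel_response(bank, dg_envelope(cat15$components[1, ]))
#' ps <- run_windows(drv, bank, participant_params())
#' posterior_mean_speed(ps)
#' @export
run_windows <- function(drive, bank, participant, interactions = NULL,
                        grid = speed_grid(), n_windows = 3,
                        mode = c("default", "literal"), logpsi = NULL) {
  mode <- match.arg(mode)
  if (inherits(drive, "spectral_envelope")) {
    drive <- channel_response(bank, drive, g = 1)
  }
  m <- participant$g^2 * drive
  if (is.null(interactions)) {
    n <- m
  } else {
    D <- if (is.matrix(interactions)) interactions
         else interaction_matrix(bank, interactions)
    n <- apply_interactions(m, D, mode)
  }
  if (is.null(logpsi)) logpsi <- speed_logpsi(bank, grid)
  ll <- speed_loglik(n, logpsi)
  ng <- length(grid)
  post <- matrix(NA_real_, n_windows + 1, ng)
  post[1, ] <- prior_density(participant, grid)
  for (k in seq_len(n_windows)) {
    post[k + 1, ] <- posterior_update(post[k, ], ll, grid)
  }
  out <- tibble(omega = rep(0:n_windows, each = ng),
                log2_v = rep(as.numeric(grid), n_windows + 1),
                posterior = as.vector(t(post)))
  structure(out, class = c("posterior_sequence", class(out)),
            grid = grid, matrix = post, m = m, n = n,
            loglik = ll, participant = participant)
}

#' Pattern nonlinearity diagnostics of the channel model
#'
#' Quantifies how the interaction kernel shapes pattern responses relative
#' to the linear prediction from components. For each pattern two numbers
#' are reported: `cross_interaction`, the cross-component part of the
#' network interaction energy `m' D m` (negative when the kernel makes the
#' components inhibit each other, as for patterns aligned with the scale
#' axis; positive for excitatory pooling along the speed axis), and
#' `rnl_model`, the model's nonlinearity ratio - the decoded mean speed for
#' the pattern divided by the mean of the decoded component speeds at the
#' final window.
#'
#' @param component_drives Named list (or matrix columns) of unit-gain
#'   component drives.
#' @param pattern_members Named list: for each pattern, the character vector
#'   of its component names.
#' @param bank A `channel_bank`.
#' @param participant A [participant_params()].
#' @param interactions An [interaction_params()].
#' @param grid,mode Passed to [run_windows()].
#' @return Tibble `pattern`, `cross_interaction`, `rnl_model`.
#' @export
pattern_nonlinearity <- function(component_drives, pattern_members, bank,
                                 participant = participant_params(),
                                 interactions = interaction_params(),
                                 grid = speed_grid(), mode = "default") {
  if (is.matrix(component_drives)) {
    component_drives <- lapply(
      setNames(seq_len(ncol(component_drives)), colnames(component_drives)),
      function(j) component_drives[, j])
  }
  D <- interaction_matrix(bank, interactions)
  logpsi <- speed_logpsi(bank, grid)
  decoded <- function(drive) {
    ps <- run_windows(drive, bank, participant, D, grid = grid, mode = mode,
                      logpsi = logpsi)
    utils::tail(posterior_mean_speed(ps)$mean_speed, 1)
  }
  comp_speed <- vapply(component_drives, decoded, 1)
  g2 <- participant$g^2
  list_rbind(map2(pattern_members, names(pattern_members), function(ids, pid) {
    ms <- lapply(component_drives[ids], function(dr) g2 * dr)
    mp <- Reduce(`+`, ms) / length(ms)
    self <- mean(vapply(ms, function(m) sum(m * as.vector(D %*% m)), 1))
    total <- sum(mp * as.vector(D %*% mp))
    tibble(pattern = pid,
           cross_interaction = total - self / length(ms),
           rnl_model = decoded(mp / g2) / mean(comp_speed[ids]))
  }))
}

#' Posterior summaries per window
#'
#' @param ps A `posterior_sequence`.
#' @return Tibble `omega`, `mode_log2_v`, `mean_log2_v`, `sd_log2_v`,
#'   `mean_speed` (deg/s).
#' @export
posterior_mean_speed <- function(ps) {
  grid <- attr(ps, "grid"); dv <- attr(grid, "dv")
  post <- attr(ps, "matrix")
  g <- as.numeric(grid)
  tibble(omega = 0:(nrow(post) - 1),
         mode_log2_v = g[apply(post, 1, which.max)],
         mean_log2_v = as.vector(post %*% g) * dv,
         sd_log2_v = sqrt(pmax(0, as.vector(post %*% g^2) * dv -
                                 (as.vector(post %*% g) * dv)^2)),
         mean_speed = as.vector(post %*% 2^g) * dv)
}
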