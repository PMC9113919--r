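# Maximum-likelihood fitting of the decoding model to per-trial window
# velocities, and AIC comparison of the interaction vs no-interaction
# variants.

# overlap of channel tuning functions with each envelope, excluding weights
# and gain (channels x stimuli); contrast included
phi_overlap <- function(bank, envelopes) {
  spec <- attr(bank, "spec")
  out <- vapply(envelopes, function(e) {
    contrast <- attr(e, "total_contrast")
    pt <- attr(e, "point")
    if (!is.null(pt)) {
      phi <- channel_density(pt["x"], pt["t"], bank$x, bank$t, spec)[, 1]
    } else {
      phi <- envelope_phi(bank, e, spec)
    }
    phi * contrast
  }, numeric(nrow(bank)))
  colnames(out) <- names(envelopes)
  out
}

#' Prepare a model-fitting context
#'
#' Precomputes the quantities that do not change while parameters are
#' optimized: the channel/envelope overlaps per stimulus and the speed
#' tuning matrix on the decoding grid.
#'
#' @param bank A `channel_bank`.
#' @param envelopes Named list of `spectral_envelope`s (names = condition
#'   ids found in the observed data).
#' @param grid A [speed_grid()].
#' @param n_windows Number of update windows after the prior stage.
#' @return List of class `fit_context`.
#' @export
fit_context <- function(bank, envelopes, grid = speed_grid(), n_windows = 3) {
  structure(list(bank = bank, overlap = phi_overlap(bank, envelopes),
                 logpsi = speed_logpsi(bank, grid), grid = grid,
                 n_windows = n_windows, stimuli = names(envelopes)),
            class = "fit_context")
}

# posterior matrices for all stimuli under one parameter set
model_posteriors <- function(ctx, params, interactions, mode = "default") {
  pp <- participant_params(params[["g"]], params[["mu_prior"]],
                           params[["sigma_prior"]])
  D <- NULL
  if (!is.null(interactions)) {
    ip <- interaction_params(alpha = params[["alpha"]],
                             sigma_e1 = params[["sigma_e1"]],
                             sigma_e2 = params[["sigma_e2"]],
                             sigma_i1 = params[["sigma_i1"]],
                             sigma_i2 = params[["sigma_i2"]])
    D <- interaction_matrix(ctx$bank, ip)
  }
  w <- ctx$bank$weight
  prior <- prior_density(pp, ctx$grid)
  dv <- attr(ctx$grid, "dv")
  lapply(setNames(ctx$stimuli, ctx$stimuli), function(s) {
    m <- pp$g^2 * w * ctx$overlap[, s]
    n <- if (is.null(D)) m else apply_interactions(m, D, mode)
    ll <- speed_loglik(n, ctx$logpsi)
    post <- matrix(NA_real_, ctx$n_windows + 1, length(prior))
    post[1, ] <- prior
    e <- exp(ll - max(ll))
    for (k in seq_len(ctx$n_windows)) {
      p <- post[k, ] * e
      z <- sum(p) * dv
      if (!is.finite(z) || z <= 0) return(NULL)
      post[k + 1, ] <- p / z
    }
    post
  })
}

#' Log-likelihood of observed window velocities under the model
#'
#' Each valid trial's window-mean velocity is mapped to log2 speed and
#' evaluated under the corresponding window posterior density (with the
#' change-of-variables Jacobian, so the density is over velocity). Trials
#' at or below `v_floor` are excluded from the log mapping and counted;
#' posterior densities below `dens_floor` are floored and counted.
#'
#' @param posteriors Named list of posterior matrices (rows omega = 0..3),
#'   e.g. from [model_posteriors()] or `attr(run_windows(...), "matrix")`.
#' @param observed Tibble `condition_id`, `window`, `mean_velocity` of
#'   per-trial window means ([window_trial_means()] output); only windows
#'   with omega >= 1 (151 ms onward) contribute.
#' @param grid The [speed_grid()] the posteriors live on.
#' @param v_floor Exclusion threshold for non-positive/near-zero velocities
#'   (deg/s).
#' @param dens_floor Density floor.
#' @return Scalar log-likelihood with attributes `n_excluded`, `n_floored`,
#'   `n_used`.
#' @export
data_loglik <- function(posteriors, observed, grid = speed_grid(),
                        v_floor = 0.25, dens_floor = 1e-12) {
  prep <- prepare_obs(observed, grid, names(posteriors), v_floor)
  fast_data_loglik(posteriors, prep, dens_floor)
}

# index observations once: per condition a (row, col) index matrix into the
# posterior and the velocity Jacobian, so repeated likelihood evaluations
# during optimization avoid any data wrangling
prepare_obs <- function(observed, grid, stimuli, v_floor = 0.25) {
  wins <- model_windows() |> filter(.data$omega >= 1)
  obs <- observed |>
    inner_join(wins, by = "window") |>
    filter(.data$condition_id %in% stimuli)
  excl <- sum(obs$mean_velocity <= v_floor)
  obs <- obs |> filter(.data$mean_velocity > v_floor)
  g <- as.numeric(grid); dv <- attr(grid, "dv")
  by_cond <- split(obs, obs$condition_id)
  prep <- lapply(by_cond, function(rows) {
    idx <- pmin(pmax(round((log2(rows$mean_velocity) - g[1]) / dv) + 1, 1),
                length(g))
    list(ij = cbind(rows$omega + 1, idx), jac = rows$mean_velocity * log(2))
  })
  structure(prep, n_excluded = excl, n_used = nrow(obs))
}

fast_data_loglik <- function(posteriors, prep, dens_floor = 1e-12) {
  total <- 0
  floored <- 0L
  for (s in names(prep)) {
    post <- posteriors[[s]]
    if (is.null(post)) {
      return(structure(-Inf, n_excluded = attr(prep, "n_excluded"),
                       n_floored = NA, n_used = attr(prep, "n_used")))
    }
    # density over velocity: p(v) = p(log2 v) / (v ln 2)
    dens <- post[prep[[s]]$ij] / prep[[s]]$jac
    floored <- floored + sum(dens < dens_floor)
    total <- total + sum(log(pmax(dens, dens_floor)))
  }
  structure(total, n_excluded = attr(prep, "n_excluded"),
            n_floored = floored, n_used = attr(prep, "n_used"))
}

default_fit_bounds <- function() {
  list(g = c(0.2, 50), mu_prior = c(0, 5), sigma_prior = c(0.1, 3),
       alpha = c(0, 10), sigma_e1 = c(0.05, 3), sigma_e2 = c(0.05, 3),
       sigma_i1 = c(0.05, 3), sigma_i2 = c(0.05, 3))
}

default_fit_values <- function() {
  ip <- interaction_params(); pp <- participant_params()
  c(g = pp$g, mu_prior = pp$mu_prior, sigma_prior = pp$sigma_prior,
    alpha = ip$alpha, sigma_e1 = ip$sigma_e1, sigma_e2 = ip$sigma_e2,
    sigma_i1 = ip$sigma_i1, sigma_i2 = ip$sigma_i2)
}

# box transform: unconstrained z -> (lo, hi)
z_to_p <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
p_to_z <- function(p, lo, hi) stats::qlogis(pmin(pmax((p - lo) / (hi - lo),
                                                      1e-8), 1 - 1e-8))

# simple hash of the observed table to guard AIC comparisons
data_fingerprint <- function(observed) {
  c(n = nrow(observed), sum = round(sum(observed$mean_velocity), 6))
}

#' Fit model parameters to observed window velocities
#'
#' Bounded derivative-free maximum likelihood: Nelder-Mead on logistic
#' box-transformed parameters, restarted from `n_starts` seeded start
#' points (the default parameter preset plus random draws within bounds);
#' the best converged start is returned with all starts logged.
#'
#' @param observed Per-trial window means (see [data_loglik()]).
#' @param ctx A [fit_context()].
#' @param free Character vector of free parameter names, a subset of
#'   `names(default_fit_values())`. Interaction parameters are only
#'   meaningful with `interactions = TRUE`.
#' @param interactions Logical: fit the variant with channel interactions?
#' @param fixed Named overrides for parameters held fixed.
#' @param bounds Named list of `c(lo, hi)` bounds.
#' @param n_starts Number of optimizer starts.
#' @param seed Integer seed for the random starts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param mode Interaction mode (see [apply_interactions()]).
#' @return Object of class `channel_fit`: fitted parameters, log-likelihood,
#'   `aic`, `k`, start log, and the data fingerprint.
#' @export
fit_channel_model <- function(observed, ctx, free = c("g", "mu_prior", "sigma_prior"),
                              interactions = FALSE, fixed = NULL,
                              bounds = default_fit_bounds(), n_starts = 8,
                              seed = 1, maxit = 400, mode = "default") {
  vals <- default_fit_values()
  if (!is.null(fixed)) vals[names(fixed)] <- unlist(fixed)
  if (!all(free %in% names(vals))) abort("Unknown free parameter name.")
  if (!interactions && any(grepl("^(alpha|sigma_[ei])", free))) {
    abort("Interaction parameters cannot be free when interactions = FALSE.")
  }
  lo <- vapply(free, function(p) bounds[[p]][1], 1)
  hi <- vapply(free, function(p) bounds[[p]][2], 1)
  prep <- prepare_obs(observed, ctx$grid, ctx$stimuli)
  obj <- function(z) {
    p <- vals
    p[free] <- z_to_p(z, lo, hi)
    posts <- model_posteriors(ctx, p, if (interactions) TRUE else NULL, mode)
    ll <- fast_data_loglik(posts, prep)
    if (!is.finite(ll)) 1e10 else -as.numeric(ll)
  }
  starts <- with_seed(seed, {
    s0 <- p_to_z(vals[free], lo, hi)
    more <- replicate(max(0, n_starts - 1),
                      p_to_z(lo + (hi - lo) * runif(length(free)), lo, hi))
    cbind(s0, matrix(more, nrow = length(free)))
  })
  runs <- map(seq_len(ncol(starts)), function(i) {
    z0 <- starts[, i]
    if (length(free) == 1) {
      o <- optim(z0, obj, method = "Brent",
                 lower = p_to_z(lo, lo, hi) - 10, upper = p_to_z(hi, lo, hi) + 10)
    } else {
      o <- optim(z0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9))
    }
    list(par = o$par, value = o$value, convergence = o$convergence)
  })
  best <- runs[[which.min(map_dbl(runs, "value"))]]
  par <- vals
  par[free] <- z_to_p(best$par, lo, hi)
  loglik <- -best$value
  k <- length(free)
  start_log <- tibble(start = seq_along(runs),
                      loglik = -map_dbl(runs, "value"),
                      convergence = map_dbl(runs, "convergence"))
  structure(list(par = par, free = free, interactions = interactions,
                 loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 starts = start_log, convergence = best$convergence,
                 fingerprint = data_fingerprint(observed), mode = mode),
            class = "channel_fit")
}

#' @export
print.channel_fit <- function(x, ...) {
  cat("<channel_fit>", if (x$interactions) "with" else "without",
      "interactions; loglik =", round(x$loglik, 2), " AIC =", round(x$aic, 2), "\n")
  print(round(x$par[x$free], 4))
  invisible(x)
}

#' @export
tidy.channel_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par),
         free = names(x$par) %in% x$free)
}

#' @export
glance.channel_fit <- function(x, ...) {
  tibble(loglik = x$loglik, AIC = x$aic, k = x$k,
         interactions = x$interactions, convergence = x$convergence)
}

#' AIC difference between interaction and no-interaction fits
#'
#' `delta = AIC_with - AIC_without`: negative values mean the interaction
#' model is preferred. Both fits must have been computed on identical data.
#'
#' @param fit_with,fit_without `channel_fit` objects on the same data.
#' @return Scalar AIC difference.
#' @export
aic_compare <- function(fit_with, fit_without) {
  if (!isTRUE(all.equal(fit_with$fingerprint, fit_without$fingerprint))) {
    abort("Fits were computed on different data sets; AIC comparison is invalid.")
  }
  fit_with$aic - fit_without$aic
}
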