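# Synthetic eye-movement cohorts with the statistical structure the
# analyses assume: ~85 ms latency, saturating rise to a condition plateau,
# across-trial square-root-of-mean velocity noise, blank-trial drift, and
# injected artifact trials. Optionally model-driven: window velocities
# sampled from the decoding model's posteriors for closed-loop recovery.

#' Ground-truth configuration for synthetic cohorts
#'
#' @param mode `"phenomenological"` (plateau-based traces; fast, for
#'   pipeline tests) or `"model_driven"` (window targets sampled from the
#'   decoding model's posteriors).
#' @param latency_mean,latency_sd Tracking latency distribution (ms).
#' @param rise_tau Time constant of the saturating-exponential velocity
#'   rise (ms).
#' @param plateau_scale Plateau velocity as a fraction of stimulus speed
#'   (eye velocity reaches only a fraction of target speed; 0.4 puts a
#'   24 deg/s stimulus near 10 deg/s).
#' @param plateau_map Optional named vector of per-condition plateau
#'   overrides (deg/s).
#' @param noise_kappa Scaling of the sqrt-of-mean law: across-trial SD of
#'   window-mean velocity is `noise_kappa * sqrt(mu)`.
#' @param sigma_floor Baseline velocity SD (deg/s), added in quadrature.
#' @param dg_late_inflation Multiplier on the SD for high-scale DG
#'   conditions in windows after 200 ms (late variability inflation).
#' @param artifact_rate Fraction of trials receiving a saccade-like
#'   artifact.
#' @param drift_amplitude Peak blank-trial post-saccadic drift (deg/s).
#' @param divergence Optional `list(condition=, onset_ms=, delta=)` adding a
#'   velocity step of `delta` deg/s from `onset_ms` to one condition (used
#'   to probe separation-time recovery).
#' @param participant A [participant_params()] (model-driven mode).
#' @param interactions An [interaction_params()] or `NULL` (model-driven).
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(mode = c("phenomenological", "model_driven"),
                         latency_mean = 85, latency_sd = 10, rise_tau = 60,
                         plateau_scale = 0.4, plateau_map = NULL,
                         noise_kappa = 1, sigma_floor = 0.2,
                         dg_late_inflation = 1.5, artifact_rate = 0.08,
                         drift_amplitude = 0.4, divergence = NULL,
                         participant = participant_params(),
                         interactions = NULL) {
  mode <- match.arg(mode)
  if (latency_mean < 50 || latency_mean > 150) {
    abort("latency_mean must lie in [50, 150] ms.")
  }
  if (artifact_rate < 0 || artifact_rate > 1) abort("artifact_rate must be in [0, 1].")
  structure(list(mode = mode, latency_mean = latency_mean,
                 latency_sd = latency_sd, rise_tau = rise_tau,
                 plateau_scale = plateau_scale, plateau_map = plateau_map,
                 noise_kappa = noise_kappa, sigma_floor = sigma_floor,
                 dg_late_inflation = dg_late_inflation,
                 artifact_rate = artifact_rate,
                 drift_amplitude = drift_amplitude, divergence = divergence,
                 participant = participant, interactions = interactions),
            class = "ground_truth")
}

# mean velocity trace for one condition (no noise), 1 kHz, t in 0..(n-1) ms
mean_trace <- function(plateau, latency, tau, n = 400, divergence = NULL) {
  t <- seq_len(n) - 1
  v <- ifelse(t > latency, plateau * (1 - exp(-(t - latency) / tau)), 0)
  if (!is.null(divergence)) {
    ramp <- pmin(pmax((t - divergence$onset_ms) / 5, 0), 1)
    v <- v + divergence$delta * ramp
  }
  v
}

# Window-coupling matrix of the (linear) preprocessing chain: entry [j, w]
# is the window-j mean response to a unit velocity offset held over window w.
# Filtering smears window boundaries, so per-window noise drawn naively
# would reach the analysis attenuated; drawing offsets as solve(A, eta)
# makes the *measured* window-mean noise match the target SD exactly.
window_noise_calibration <- function(duration_ms, cfg = trace_config(),
                                     windows = ofr_windows()) {
  t <- seq_len(duration_ms) - 1
  nw <- nrow(windows)
  A <- matrix(0, nw, nw)
  for (w in seq_len(nw)) {
    v <- as.numeric(t >= windows$start_ms[w] & t <= windows$end_ms[w])
    vv <- preprocess_one(cumsum(v) / 1000, "right", cfg)
    for (j in seq_len(nw)) {
      A[j, w] <- mean(vv[t >= windows$start_ms[j] & t <= windows$end_ms[j]])
    }
  }
  A
}

condition_plateaus <- function(truth, components, patterns = NULL) {
  base <- setNames(truth$plateau_scale * components$v0, components$id)
  if (!is.null(patterns)) {
    pat <- vapply(seq_len(nrow(patterns)), function(i) {
      mean(base[patterns$component_ids[[i]]])
    }, 1)
    base <- c(base, setNames(pat, patterns$id))
  }
  if (!is.null(truth$plateau_map)) {
    base[names(truth$plateau_map)] <- truth$plateau_map
  }
  base
}

#' Generate a synthetic eye-movement cohort
#'
#' Produces raw eye-position trials (1 kHz, 400 ms) for each condition and
#' participant: per trial the latency is drawn from the latency
#' distribution, velocity rises with a saturating exponential toward the
#' condition plateau, per-window offsets enforce the across-trial
#' square-root-of-mean SD law (inflated for high-scale DG conditions after
#' 200 ms), positions are the integral of velocity plus the shared
#' post-saccadic drift, saccade-like artifacts are injected at
#' `artifact_rate`, and left/right directions are balanced. Blank trials
#' contain the drift only.
#'
#' @param truth A [ground_truth()].
#' @param components Component tibble (a [stimulus_catalog()] subset).
#' @param patterns Optional pattern tibble; pattern plateaus default to the
#'   linear component-average rule.
#' @param n_trials Trials per condition (per participant).
#' @param n_blanks Blank trials per participant.
#' @param participants Number of participants.
#' @param duration_ms Samples per trial.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Tibble of raw trials: `participant`, `trial_id`, `condition_id`,
#'   `direction`, `is_blank`, `time_ms`, `position` (deg); the ground truth
#'   is echoed in the `ground_truth` attribute.
#' @export
generate_cohort <- function(truth, components, patterns = NULL, n_trials = 40,
                            n_blanks = n_trials, participants = 1,
                            duration_ms = 400, seed = 1) {
  if (n_blanks < 1) abort("The pipeline requires blank trials (n_blanks >= 1).")
  plateaus <- condition_plateaus(truth, components, patterns)
  conds <- names(plateaus)
  scale_rank <- rank(components$sf0 * components$tf0)
  high_scale <- setNames(scale_rank > (2 / 3) * nrow(components), components$id)
  is_dg <- setNames(components$stimulus_type == "DG", components$id)
  wins <- ofr_windows()
  t <- seq_len(duration_ms) - 1
  Ainv <- solve(window_noise_calibration(duration_ms, windows = wins))

  with_seed(seed, {
    drift <- truth$drift_amplitude * exp(-t / 150)
    rows <- list()
    for (pp in seq_len(participants)) {
      for (cond in c(conds, "blank")) {
        blank <- cond == "blank"
        ntr <- if (blank) n_blanks else n_trials
        div <- NULL
        if (!blank && !is.null(truth$divergence) &&
              identical(truth$divergence$condition, cond)) {
          div <- truth$divergence
        }
        mu_trace <- if (blank) rep(0, duration_ms) else
          mean_trace(plateaus[[cond]], truth$latency_mean, truth$rise_tau,
                     duration_ms, div)
        mu_w <- vapply(seq_len(nrow(wins)), function(w) {
          mean(mu_trace[t >= wins$start_ms[w] & t <= wins$end_ms[w]])
        }, 1)
        sd_w <- sqrt((truth$noise_kappa * sqrt(pmax(mu_w, 0)))^2 +
                       truth$sigma_floor^2)
        if (!blank && isTRUE(is_dg[cond]) && isTRUE(high_scale[cond])) {
          sd_w[wins$start_ms > 200] <- sd_w[wins$start_ms > 200] *
            truth$dg_late_inflation
        }
        for (tr in seq_len(ntr)) {
          if (blank) {
            v <- drift + 0.15 * stats::filter(rnorm(duration_ms), rep(0.2, 5),
                                              sides = 2)
            v[is.na(v)] <- 0
          } else {
            lat <- rnorm(1, truth$latency_mean, truth$latency_sd)
            d <- mean_trace(plateaus[[cond]], lat, truth$rise_tau,
                            duration_ms, div)
            targ <- mu_w + drop(Ainv %*% rnorm(nrow(wins), 0, sd_w))
            v <- d
            for (w in seq_len(nrow(wins))) {
              sel <- t >= wins$start_ms[w] & t <= wins$end_ms[w]
              v[sel] <- v[sel] + (targ[w] - mean(d[sel]))
            }
            v <- v + drift
            if (runif(1) < truth$artifact_rate) {
              onset <- sample(50:330, 1)
              width <- sample(20:40, 1)
              amp <- runif(1, 120, 300) * sample(c(-1, 1), 1)
              idx <- onset:(onset + width - 1)
              v[idx] <- v[idx] + amp * sin(pi * seq_along(idx) / width)
            }
          }
          dir <- if (tr %% 2 == 0) "left" else "right"
          pos <- cumsum(v) / 1000
          if (dir == "left") pos <- -pos
          rows[[length(rows) + 1]] <- tibble(
            participant = pp,
            trial_id = sprintf("p%d_%s_%03d", pp, cond, tr),
            condition_id = cond, direction = dir, is_blank = blank,
            time_ms = t, position = pos)
        }
      }
    }
    out <- list_rbind(rows)
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Simulate per-window trial velocities from the decoding model
#'
#' For each stimulus, runs the posterior recursion and draws `n_trials`
#' velocities per window from the window's posterior density over speed
#' (prior for omega = 0). This is the model-driven generator used for
#' closed-loop parameter recovery.
#'
#' @param drives Named list or matrix of unit-gain drives (see
#'   [stimulus_drive()]), one per condition.
#' @param bank A `channel_bank`.
#' @param participant A [participant_params()].
#' @param interactions An [interaction_params()] or `NULL`.
#' @param n_trials Trials per condition and window.
#' @param grid A [speed_grid()].
#' @param n_windows Update windows after the prior stage.
#' @param seed Integer seed.
#' @param mode Interaction mode.
#' @return Tibble `condition_id`, `trial_id`, `window`, `mean_velocity`
#'   (deg/s), matching the [window_trial_means()] layout used by
#'   [data_loglik()].
#' @export
forward_simulate_responses <- function(drives, bank, participant,
                                       interactions = NULL, n_trials = 150,
                                       grid = speed_grid(), n_windows = 3,
                                       seed = 1, mode = "default") {
  if (is.matrix(drives)) {
    drives <- lapply(setNames(seq_len(ncol(drives)), colnames(drives)),
                     function(j) drives[, j])
  }
  wins <- model_windows()
  dv <- attr(grid, "dv"); g <- as.numeric(grid)
  lp <- speed_logpsi(bank, grid)
  with_seed(seed, {
    out <- map(names(drives), function(s) {
      ps <- run_windows(drives[[s]], bank, participant, interactions,
                        grid = grid, n_windows = n_windows, mode = mode,
                        logpsi = lp)
      post <- attr(ps, "matrix")
      map(seq_len(nrow(post)), function(k) {
        pr <- post[k, ] / sum(post[k, ])
        idx <- sample.int(length(g), n_trials, replace = TRUE, prob = pr)
        lv <- g[idx] + runif(n_trials, -dv / 2, dv / 2)
        tibble(condition_id = s,
               trial_id = sprintf("%s_w%d_%03d", s, k - 1, seq_len(n_trials)),
               window = wins$window[k], mean_velocity = 2^lv)
      }) |> list_rbind()
    })
    list_rbind(out)
  })
}
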