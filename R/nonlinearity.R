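# Linear predictions for pattern stimuli, the nonlinearity ratio, and
# separation-time estimation between observed and predicted tracking.

#' Linear prediction of a pattern response from its components
#'
#' The linear prediction is the sample-wise arithmetic mean of the mean
#' tracking responses to each component presented alone.
#'
#' @param component_trials Cleaned trial tibble covering the pattern's
#'   components (`condition_id`, `trial_id`, `time_ms`, `velocity`).
#' @param component_ids Character vector of the pattern's component ids.
#' @return Tibble `time_ms`, `velocity` (predicted mean trace).
#' @export
linear_prediction <- function(component_trials, component_ids) {
  per_comp <- component_trials |>
    filter(.data$condition_id %in% component_ids) |>
    group_by(.data$condition_id, .data$time_ms) |>
    summarise(velocity = mean(.data$velocity), .groups = "drop")
  found <- unique(per_comp$condition_id)
  if (!setequal(found, component_ids)) {
    abort("Component trials missing for some pattern components.")
  }
  counts <- per_comp |> count(.data$condition_id)
  if (length(unique(counts$n)) != 1) {
    abort("Component traces are not on a common time base.")
  }
  per_comp |>
    group_by(.data$time_ms) |>
    summarise(velocity = mean(.data$velocity), .groups = "drop")
}

#' Pseudo-trials realizing the linear prediction's variability
#'
#' The linear prediction is a mean trace; to give it an empirical trial
#' population (needed for binned t tests), pseudo-trials are formed by
#' averaging one randomly drawn trial per component.
#'
#' @param component_trials Cleaned trial tibble for the components.
#' @param component_ids The pattern's component ids.
#' @param n_pseudo Number of pseudo-trials.
#' @param seed Integer seed.
#' @return Tibble `trial_id`, `time_ms`, `velocity`.
#' @export
prediction_pseudo_trials <- function(component_trials, component_ids,
                                     n_pseudo = 150, seed = 1) {
  comp <- component_trials |> filter(.data$condition_id %in% component_ids)
  ids_by_comp <- comp |>
    distinct(.data$condition_id, .data$trial_id) |>
    group_by(.data$condition_id) |>
    group_split()
  times <- sort(unique(comp$time_ms))
  # matrix lookup per component: time x trial
  mats <- map(ids_by_comp, function(d) {
    cc <- d$condition_id[1]
    sub <- comp |> filter(.data$condition_id == cc) |>
      arrange(.data$trial_id, .data$time_ms)
    matrix(sub$velocity, nrow = length(times),
           dimnames = list(NULL, unique(sub$trial_id)))
  })
  with_seed(seed, {
    out <- map(seq_len(n_pseudo), function(i) {
      tr <- map(mats, function(m) m[, sample(ncol(m), 1)])
      tibble(trial_id = sprintf("pseudo_%03d", i), time_ms = times,
             velocity = Reduce(`+`, tr) / length(tr))
    })
    list_rbind(out)
  })
}

#' Nonlinearity ratio between observed and predicted responses
#'
#' `R_NL = e_obs / e_pred`, the ratio of observed pattern window-mean eye
#' velocity to the linear prediction's window mean. 1 means the pattern
#' response equals the component average; above/below 1 means supra- or
#' sub-linear integration.
#'
#' @param observed_trials Cleaned trials for the pattern condition.
#' @param predicted Predicted trace from [linear_prediction()].
#' @param windows Analysis windows, default [ofr_windows()].
#' @return Tibble `window`, `e_obs`, `e_pred`, `r_nl`, `defined` (`FALSE`
#'   where `e_pred <= 0` leaves the ratio undefined).
#' @export
r_nl <- function(observed_trials, predicted, windows = ofr_windows()) {
  obs <- observed_trials |>
    mutate(condition_id = "obs") |>
    window_trial_means(windows) |>
    group_by(.data$window) |>
    summarise(e_obs = mean(.data$mean_velocity), .groups = "drop")
  pred <- pmap(windows, function(window, start_ms, end_ms) {
    tibble(window = window,
           e_pred = mean(predicted$velocity[predicted$time_ms >= start_ms &
                                              predicted$time_ms <= end_ms]))
  }) |> list_rbind()
  obs |>
    inner_join(pred, by = "window") |>
    mutate(defined = .data$e_pred > 0,
           r_nl = ifelse(.data$defined, .data$e_obs / .data$e_pred, NA_real_))
}

# vectorized Welch two-sample t test over columns of two matrices
welch_columns <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(p)] <- 1 # zero-variance identical bins
  p
}

#' First time of significant separation between observed and predicted
#'
#' Bins both trial populations into 5-ms windows, runs a Welch t test per
#' bin, and reports the start of the first bin that opens a run of at least
#' `k` consecutive significant bins. `k = 3` guards against isolated false
#' positives among the ~80 bins; `k = 1` reproduces the literal
#' first-significant-bin rule.
#'
#' @param observed_trials,predicted_trials Trial tibbles (`trial_id`,
#'   `time_ms`, `velocity`); the predicted side is typically
#'   [prediction_pseudo_trials()].
#' @param alpha Significance level per bin.
#' @param k Required run length of consecutive significant bins.
#' @param bin_ms Bin width (ms).
#' @param t_range Time range analysed (ms).
#' @return Tibble `time_ms` (NA when no separation), `defined`, and the
#'   per-bin p values in the `bins` attribute.
#' @export
separation_time <- function(observed_trials, predicted_trials, alpha = 0.05,
                            k = 3, bin_ms = 5, t_range = c(0, 400)) {
  edges <- seq(t_range[1], t_range[2], by = bin_ms)
  binmat <- function(tr) {
    tr <- tr |> filter(.data$time_ms >= t_range[1], .data$time_ms < t_range[2])
    tr$bin <- findInterval(tr$time_ms, edges, rightmost.closed = FALSE)
    agg <- tr |>
      group_by(.data$trial_id, .data$bin) |>
      summarise(v = mean(.data$velocity), .groups = "drop")
    tidyr::pivot_wider(agg, names_from = "bin", values_from = "v") |>
      select(-"trial_id") |>
      as.matrix()
  }
  A <- binmat(observed_trials); B <- binmat(predicted_trials)
  if (nrow(A) < 2 || nrow(B) < 2) abort("Need >= 2 trials per side per bin.")
  nb <- min(ncol(A), ncol(B))
  p <- welch_columns(A[, seq_len(nb), drop = FALSE], B[, seq_len(nb), drop = FALSE])
  sig <- p < alpha
  run <- rle(sig)
  starts <- cumsum(c(1, head(run$lengths, -1)))
  hit <- which(run$values & run$lengths >= k)
  out <- if (length(hit) == 0) {
    tibble(time_ms = NA_real_, defined = FALSE)
  } else {
    tibble(time_ms = edges[starts[hit[1]]], defined = TRUE)
  }
  attr(out, "bins") <- tibble(start_ms = edges[seq_len(nb)], p = p)
  out
}

#' Bootstrap trimmed-mean comparison of two samples
#'
#' Nonparametric two-sided test of a difference in trimmed means based on
#' bootstrap resampling (1000 samples by default), as used to compare
#' linear-nonlinear separation times between stimulus types.
#'
#' @param times_a,times_b Numeric samples.
#' @param reps Bootstrap replicates.
#' @param trim Trim fraction in \[0, 0.25\] applied to each tail.
#' @param seed Integer seed.
#' @return Tibble `estimate` (trimmed-mean difference), `p_value`, `reps`.
#' @export
bootstrap_trimmed_mean_test <- function(times_a, times_b, reps = 1000,
                                        trim = 0.2, seed = 1) {
  if (length(times_a) == 0 || length(times_b) == 0) abort("Empty sample.")
  if (trim < 0 || trim > 0.25) abort("trim must lie in [0, 0.25].")
  if (reps < 100) warn("Fewer than 100 bootstrap replicates; p value is unstable.")
  est <- mean(times_a, trim = trim) - mean(times_b, trim = trim)
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      mean(sample(times_a, replace = TRUE), trim = trim) -
        mean(sample(times_b, replace = TRUE), trim = trim)
    }, 1)
  })
  p <- 2 * min((sum(boot <= 0) + 1) / (reps + 1),
               (sum(boot >= 0) + 1) / (reps + 1))
  tibble(estimate = est, p_value = min(p, 1), reps = reps)
}
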