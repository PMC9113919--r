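# Eye-trace preprocessing: position filtering, differentiation, artifact
# rejection, blank subtraction, and 50-ms window statistics.

#' Trace preprocessing configuration
#'
#' @param pos_cutoff_hz Low-pass cutoff for eye position (Hz).
#' @param vel_cutoff_hz Low-pass cutoff for eye velocity (Hz).
#' @param order Butterworth filter order.
#' @param diff_half_ms Half-span of the central difference (ms); velocity at
#'   time t uses positions at t +/- this, i.e. samples 10 ms apart by default.
#' @param fs_hz Sampling rate (Hz).
#' @param vel_limit,acc_limit Artifact thresholds: absolute velocity (deg/s)
#'   and acceleration (deg/s^2) that flag a trial when exceeded for at least
#'   `sustain_ms` consecutive milliseconds.
#' @param sustain_ms Minimum duration of a threshold crossing to count.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(pos_cutoff_hz = 40, vel_cutoff_hz = 30, order = 5,
                         diff_half_ms = 5, fs_hz = 1000,
                         vel_limit = 80, acc_limit = 5000, sustain_ms = 5) {
  structure(list(pos_cutoff_hz = pos_cutoff_hz, vel_cutoff_hz = vel_cutoff_hz,
                 order = order, diff_half_ms = diff_half_ms, fs_hz = fs_hz,
                 vel_limit = vel_limit, acc_limit = acc_limit,
                 sustain_ms = sustain_ms),
            class = "trace_config")
}

# zero-phase Butterworth low-pass of one vector, with odd-reflection
# padding to suppress the start/end transients of the forward-backward pass
lowpass <- function(x, cutoff_hz, fs_hz, order) {
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  n <- length(x)
  k <- min(n - 1, 3 * round(fs_hz / cutoff_hz) + 3 * order)
  head_pad <- 2 * x[1] - x[(k + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - k)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(k + 1):(k + n)]
}

preprocess_one <- function(position, direction, cfg) {
  p <- lowpass(position, cfg$pos_cutoff_hz, cfg$fs_hz, cfg$order)
  h <- cfg$diff_half_ms
  n <- length(p)
  v <- rep(NA_real_, n)
  idx <- (h + 1):(n - h)
  v[idx] <- (p[idx + h] - p[idx - h]) / (2 * h / cfg$fs_hz * 1000) * 1000
  v[seq_len(h)] <- v[h + 1]
  v[(n - h + 1):n] <- v[n - h]
  v <- lowpass(v, cfg$vel_cutoff_hz, cfg$fs_hz, cfg$order)
  if (identical(direction, "left")) -v else v
}

#' Preprocess raw eye-position trials into velocity traces
#'
#' Positions are low-pass filtered (zero-phase Butterworth, 40 Hz default),
#' differentiated by central difference with samples 10 ms apart (one
#' velocity estimate per millisecond), and the velocity is filtered again
#' (30 Hz default). Leftward-motion trials are sign-inverted so tracking in
#' the stimulus direction is positive.
#'
#' @param raw Tidy tibble of raw trials: `trial_id`, `condition_id`,
#'   `direction` (`"left"`/`"right"`), `time_ms`, `position` (deg), and
#'   optionally `is_blank`.
#' @param cfg A [trace_config()].
#' @return Tibble `trial_id`, `condition_id`, `direction`, `is_blank`,
#'   `time_ms`, `velocity` (deg/s). Trials shorter than three filter lengths
#'   are dropped with a warning naming them.
#' @export
preprocess_trials <- function(raw, cfg = trace_config()) {
  if (!"is_blank" %in% names(raw)) raw$is_blank <- FALSE
  min_len <- 3 * (cfg$order + 1) + 2 * cfg$diff_half_ms
  raw |>
    group_by(.data$trial_id, .data$condition_id, .data$direction, .data$is_blank) |>
    arrange(.data$time_ms, .by_group = TRUE) |>
    group_modify(function(d, key) {
      if (nrow(d) < min_len) {
        warn(sprintf("Trial %s too short for filter warm-up (%d samples); dropped.",
                     key$trial_id, nrow(d)))
        return(tibble(time_ms = numeric(), velocity = numeric()))
      }
      tibble(time_ms = d$time_ms,
             velocity = preprocess_one(d$position, key$direction, cfg))
    }) |>
    ungroup()
}

flag_artifact <- function(v, cfg) {
  acc <- c(diff(v) * cfg$fs_hz, 0)
  bad <- abs(v) > cfg$vel_limit | abs(acc) > cfg$acc_limit
  if (!any(bad)) return(FALSE)
  r <- rle(bad)
  any(r$lengths[r$values] >= cfg$sustain_ms)
}

#' Reject artifact trials and subtract the mean blank drift
#'
#' Trials whose velocity or acceleration exceeds the configured thresholds
#' for a sustained run (saccades, blinks, large oscillations) are flagged
#' invalid. The sample-wise mean velocity of the blank trials (residual
#' post-saccadic drift) is subtracted from every valid stimulus trial.
#'
#' @param velocity Tibble from [preprocess_trials()]; blank trials are the
#'   rows with `is_blank == TRUE`.
#' @param cfg A [trace_config()].
#' @return List of class `trial_set`: `trials` (cleaned valid trials),
#'   `rejected` (tibble of trial ids with reasons), `blank_mean` (tibble
#'   `time_ms`, `velocity`) and `rejection_fraction`.
#' @export
reject_and_subtract <- function(velocity, cfg = trace_config()) {
  blanks <- velocity |> filter(.data$is_blank)
  stim <- velocity |> filter(!.data$is_blank)
  if (nrow(blanks) == 0) abort("Blank subtraction needs at least one blank trial.")
  blank_mean <- blanks |>
    group_by(.data$time_ms) |>
    summarise(velocity = mean(.data$velocity), .groups = "drop")

  flags <- stim |>
    group_by(.data$trial_id, .data$condition_id) |>
    summarise(artifact = flag_artifact(.data$velocity, cfg), .groups = "drop")
  rejected <- flags |> filter(.data$artifact) |>
    transmute(.data$trial_id, .data$condition_id, reason = "artifact")
  keep <- flags |> filter(!.data$artifact)
  if (nrow(keep) == 0) abort("All trials were rejected as artifacts.")

  cleaned <- stim |>
    semi_join(keep, by = c("trial_id", "condition_id")) |>
    left_join(blank_mean |> rename(blank_v = "velocity"), by = "time_ms") |>
    mutate(velocity = .data$velocity - ifelse(is.na(.data$blank_v), 0, .data$blank_v)) |>
    select(-"blank_v")

  structure(list(trials = cleaned, rejected = rejected, blank_mean = blank_mean,
                 rejection_fraction = nrow(rejected) / nrow(flags)),
            class = "trial_set")
}

#' The five 50-ms analysis windows
#'
#' Successive windows binning the response between 50 and 300 ms after
#' stimulus onset; the first (51-100 ms) covers the pre-response baseline,
#' the next two the open-loop phase.
#'
#' @return Tibble with `window` (label), `start_ms`, `end_ms`.
#' @export
ofr_windows <- function() {
  start <- c(51, 101, 151, 201, 251)
  tibble(window = sprintf("%d-%d", start, start + 49),
         start_ms = start, end_ms = start + 49)
}

#' Per-trial mean velocity in each analysis window
#'
#' @param trials Cleaned trial tibble (or a `trial_set`).
#' @param windows Window tibble; defaults to [ofr_windows()].
#' @return Tibble `condition_id`, `trial_id`, `window`, `mean_velocity`.
#' @export
window_trial_means <- function(trials, windows = ofr_windows()) {
  if (inherits(trials, "trial_set")) trials <- trials$trials
  pmap(windows, function(window, start_ms, end_ms) {
    trials |>
      filter(.data$time_ms >= start_ms, .data$time_ms <= end_ms) |>
      group_by(.data$condition_id, .data$trial_id) |>
      summarise(mean_velocity = mean(.data$velocity), .groups = "drop") |>
      mutate(window = window)
  }) |>
    list_rbind() |>
    select("condition_id", "trial_id", "window", "mean_velocity")
}

#' Windowed Gaussian statistics of tracking responses
#'
#' For each condition and 50-ms window, fits a Gaussian to the distribution
#' of per-trial mean velocities by moment matching (equal to the maximum
#' likelihood fit) and derives the coefficient of variation `cv = sigma/mu`
#' (defined only for `mu > 0`) and the shot-noise deviation
#' `sigma_d = sigma - sqrt(mu)`, which is ~0 when across-trial variability
#' follows the square-root-of-mean law.
#'
#' @param trials Cleaned trial tibble or `trial_set`.
#' @param windows Window tibble; defaults to [ofr_windows()].
#' @param low_n Cells with fewer valid trials than this are flagged.
#' @return Tibble `condition_id`, `window`, `n`, `mu`, `sigma`, `cv`,
#'   `sigma_d`, `low_n`.
#' @export
window_stats <- function(trials, windows = ofr_windows(), low_n = 5) {
  window_trial_means(trials, windows) |>
    group_by(.data$condition_id, .data$window) |>
    summarise(n = dplyr::n(),
              mu = mean(.data$mean_velocity),
              sigma = if (dplyr::n() > 1) sd(.data$mean_velocity) else 0,
              .groups = "drop") |>
    mutate(cv = ifelse(.data$mu > 0, .data$sigma / .data$mu, NA_real_),
           sigma_d = ifelse(.data$mu >= 0,
                            .data$sigma - sqrt(pmax(.data$mu, 0)), NA_real_),
           low_n = .data$n < low_n)
}
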