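mk_raw <- function(position, id = "t1", cond = "c1", dir = "right",
                   blank = FALSE) {
  tibble::tibble(trial_id = id, condition_id = cond, direction = dir,
                 is_blank = blank, time_ms = seq_along(position) - 1,
                 position = position)
}

test_that("preprocessing recovers constant velocity and preserves zeros", {
  ramp <- mk_raw(0.01 * (0:399))
  v <- preprocess_trials(ramp)
  expect_equal(mean(v$velocity[100:300]), 10, tolerance = 0.05)
  z <- preprocess_trials(mk_raw(rep(0, 400)))
  expect_equal(max(abs(z$velocity)), 0, tolerance = 1e-12)
  # leftward trials are sign-aligned
  vl <- preprocess_trials(mk_raw(-0.01 * (0:399), dir = "left"))
  expect_equal(mean(vl$velocity[100:300]), 10, tolerance = 0.05)
})

test_that("a 60 Hz sinusoid is attenuated by the analytic filter cascade gain", {
  fs <- 1000; f <- 60; A <- 0.5; n <- 2000
  raw <- mk_raw(A * sin(2 * pi * f * (0:(n - 1)) / fs))
  v <- preprocess_trials(raw)$velocity
  idx <- 500:1500
  tt <- idx / fs
  X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  amp <- sqrt(sum(qr.coef(qr(X), v[idx + 1])^2))
  # oracle: central-difference gain times the squared (zero-phase) magnitude
  # of each bilinear-prewarped Butterworth stage
  bw <- function(f, fc, ord = 5) {
    1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * ord))
  }
  expected <- A * (sin(2 * pi * f * 0.005) / 0.005) * bw(f, 40)^2 * bw(f, 30)^2
  expect_equal(amp, expected, tolerance = 0.05 * expected)
})

test_that("preprocessing is linear in the input", {
  set.seed(4)
  p <- cumsum(rnorm(500)) / 100
  v1 <- preprocess_trials(mk_raw(p))$velocity
  v3 <- preprocess_trials(mk_raw(3 * p))$velocity
  expect_equal(v3, 3 * v1, tolerance = 1e-9)
})

test_that("short traces are dropped with a reason", {
  expect_warning(out <- preprocess_trials(mk_raw(rep(0, 20))), "too short")
  expect_equal(nrow(out), 0)
})

test_that("artifact trials are flagged and blank subtraction is exact", {
  set.seed(9)
  drift <- 0.5 * exp(-(0:399) / 150)
  blanks <- purrr::list_rbind(purrr::map(1:5, function(i) {
    mk_raw(cumsum(drift + rnorm(400, 0, 0.05)) / 1000,
           id = paste0("b", i), cond = "blank", blank = TRUE)
  }))
  clean <- mk_raw(cumsum(drift + 8 * (0:399 > 100)) / 1000, id = "ok")
  sacc_v <- drift + 8 * (0:399 > 100)
  sacc_v[200:230] <- sacc_v[200:230] + 200 * sin(pi * (0:30) / 30)
  sacc <- mk_raw(cumsum(sacc_v) / 1000, id = "sacc")
  vel <- preprocess_trials(dplyr::bind_rows(blanks, clean, sacc))
  ts <- reject_and_subtract(vel)
  expect_equal(ts$rejected$trial_id, "sacc")
  expect_equal(ts$rejection_fraction, 0.5)

  # a stimulus trial identical to the mean blank comes out as zeros
  bm <- ts$blank_mean
  echo_pos <- cumsum(bm$velocity) / 1000
  vel2 <- dplyr::bind_rows(vel |> dplyr::filter(is_blank),
                           preprocess_trials(mk_raw(echo_pos, id = "echo")))
  ts2 <- reject_and_subtract(vel2)
  echo_v <- ts2$trials$velocity
  expect_lt(max(abs(echo_v[30:370])), 0.02)

  expect_error(reject_and_subtract(vel |> dplyr::filter(!is_blank)),
               "blank trial")
})

test_that("window statistics use the five exact bins and moment-matched Gaussians", {
  w <- ofr_windows()
  expect_equal(w$start_ms, c(51, 101, 151, 201, 251))
  expect_equal(w$end_ms, c(100, 150, 200, 250, 300))
  # no sample assigned to two windows; constant trials give sigma = 0
  trials <- purrr::list_rbind(purrr::map(1:6, function(i) {
    tibble::tibble(trial_id = paste0("t", i), condition_id = "c",
                   time_ms = 0:399, velocity = 5)
  }))
  wm <- window_trial_means(trials)
  expect_equal(nrow(wm), 6 * 5)
  ws <- window_stats(trials)
  expect_true(all(ws$mu == 5))
  expect_true(all(ws$sigma == 0))
  expect_true(all(ws$cv == 0))
  expect_false(any(ws$low_n))

  # Gaussian moments recovered from sampled trials
  set.seed(21)
  nt <- 150
  trials2 <- purrr::list_rbind(purrr::map(seq_len(nt), function(i) {
    tibble::tibble(trial_id = paste0("t", i), condition_id = "c",
                   time_ms = 0:399, velocity = rnorm(1, 4, 1))
  }))
  ws2 <- window_stats(trials2)
  expect_true(all(abs(ws2$mu - 4) < 0.25))
  expect_true(all(abs(ws2$sigma - 1) < 0.2))
  # low-n flag
  ws3 <- window_stats(trials2 |> dplyr::filter(trial_id %in% c("t1", "t2")))
  expect_true(all(ws3$low_n))
})
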