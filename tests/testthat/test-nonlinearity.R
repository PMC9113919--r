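mk_trials <- function(cond, n, vfun, seed = 1, sd = 0) {
  withr::with_seed(seed, {
    purrr::list_rbind(purrr::map(seq_len(n), function(i) {
      t <- 0:399
      tibble::tibble(condition_id = cond, trial_id = sprintf("%s_%02d", cond, i),
                     time_ms = t, velocity = vfun(t) + rnorm(length(t), 0, sd))
    }))
  })
}

test_that("linear predictions are sample-wise component means", {
  tr <- dplyr::bind_rows(
    mk_trials("a", 3, function(t) rep(3, length(t))),
    mk_trials("b", 3, function(t) rep(6, length(t))),
    mk_trials("c", 3, function(t) rep(9, length(t))))
  lp <- linear_prediction(tr, c("a", "b", "c"))
  expect_true(all(lp$velocity == 6))
  # identical components reproduce the trace
  tr2 <- dplyr::bind_rows(
    mk_trials("a", 2, function(t) sin(t / 30)),
    mk_trials("b", 2, function(t) sin(t / 30)))
  lp2 <- linear_prediction(tr2, c("a", "b"))
  expect_equal(lp2$velocity, sin((0:399) / 30), tolerance = 1e-12)
  # random traces equal an independent brute-force mean
  tr3 <- dplyr::bind_rows(
    mk_trials("a", 4, function(t) t / 100, seed = 2, sd = 1),
    mk_trials("b", 4, function(t) t / 50, seed = 3, sd = 1))
  lp3 <- linear_prediction(tr3, c("a", "b"))
  brute <- sapply(0:399, function(tm) {
    mean(c(mean(tr3$velocity[tr3$condition_id == "a" & tr3$time_ms == tm]),
           mean(tr3$velocity[tr3$condition_id == "b" & tr3$time_ms == tm])))
  })
  expect_equal(lp3$velocity, brute, tolerance = 1e-12)
  # mismatched time bases are rejected
  bad <- dplyr::bind_rows(mk_trials("a", 2, function(t) t),
                          mk_trials("b", 2, function(t) t) |>
                            dplyr::filter(time_ms < 300))
  expect_error(linear_prediction(bad, c("a", "b")), "time base")
  expect_error(linear_prediction(bad, c("a", "zz")), "missing")
})

test_that("prediction commutes with window averaging", {
  tr <- dplyr::bind_rows(
    mk_trials("a", 5, function(t) t / 40, seed = 4, sd = 0.5),
    mk_trials("b", 5, function(t) sqrt(t), seed = 5, sd = 0.5))
  lp <- linear_prediction(tr, c("a", "b"))
  # window-then-mean
  wm <- window_trial_means(tr) |>
    dplyr::group_by(condition_id, window) |>
    dplyr::summarise(m = mean(mean_velocity), .groups = "drop") |>
    dplyr::group_by(window) |>
    dplyr::summarise(m = mean(m), .groups = "drop")
  # mean-then-window
  mw <- purrr::pmap(ofr_windows(), function(window, start_ms, end_ms) {
    tibble::tibble(window = window,
                   m = mean(lp$velocity[lp$time_ms >= start_ms &
                                          lp$time_ms <= end_ms]))
  }) |> purrr::list_rbind()
  expect_equal(dplyr::arrange(wm, window)$m, dplyr::arrange(mw, window)$m,
               tolerance = 1e-12)
})

test_that("nonlinearity ratios behave as ratios and respect scaling", {
  obs <- mk_trials("p", 6, function(t) rep(6, length(t)))
  pred <- tibble::tibble(time_ms = 0:399, velocity = rep(6, 400))
  r1 <- r_nl(obs, pred)
  expect_true(all(r1$r_nl == 1))
  r2 <- r_nl(obs |> dplyr::mutate(velocity = 1.2 * velocity), pred)
  expect_equal(r2$r_nl, rep(1.2, 5), tolerance = 1e-12)
  # scale invariance: multiplying all traces by a > 0 leaves R_NL unchanged
  a <- 3.7
  r3 <- r_nl(obs |> dplyr::mutate(velocity = a * velocity),
             pred |> dplyr::mutate(velocity = a * velocity))
  expect_equal(r3$r_nl, r1$r_nl, tolerance = 1e-12)
  # undefined when the prediction is non-positive
  r4 <- r_nl(obs, pred |> dplyr::mutate(velocity = 0))
  expect_true(all(!r4$defined))
  expect_true(all(is.na(r4$r_nl)))
})

test_that("separation times have controlled false alarms under the null", {
  runs <- purrr::map_lgl(1:20, function(s) {
    a <- mk_trials("o", 150, function(t) 5 + t / 100, seed = 100 + s, sd = 1.5)
    b <- mk_trials("p", 150, function(t) 5 + t / 100, seed = 200 + s, sd = 1.5)
    separation_time(a, b)$defined
  })
  expect_gte(mean(!runs), 0.9)
})

test_that("an injected divergence is localized and monotone in size", {
  sep_for <- function(delta, seed) {
    a <- mk_trials("o", 150, function(t) 5 + delta * (t >= 180), seed = 300 + seed,
                   sd = 1.5)
    b <- mk_trials("p", 150, function(t) rep(5, length(t)), seed = 400 + seed,
                   sd = 1.5)
    separation_time(a, b)$time_ms
  }
  t2 <- sep_for(2, 1)
  expect_lte(abs(t2 - 180), 10)
  # monotonicity: larger divergence separates no later (20 seeds)
  mono <- purrr::map_lgl(1:20, function(s) {
    s_small <- sep_for(1.0, 10 + s)
    s_big <- sep_for(4.0, 10 + s)
    is.na(s_small) || (!is.na(s_big) && s_big <= s_small)
  })
  expect_true(all(mono))
  # translation equivariance within bin resolution
  sh <- 60
  a <- mk_trials("o", 150, function(t) 5 + 2 * (t >= 180 + sh), seed = 991, sd = 1.5)
  b <- mk_trials("p", 150, function(t) rep(5, length(t)), seed = 992, sd = 1.5)
  t_sh <- separation_time(a, b)$time_ms
  expect_lte(abs(t_sh - (180 + sh)), 10)
  expect_error(separation_time(a[1:400, ], b), ">= 2 trials")
})

test_that("bootstrap trimmed-mean tests behave at both extremes", {
  x <- c(151, 160, 149, 172, 168, 155, 162, 170, 158, 166)
  same <- bootstrap_trimmed_mean_test(x, x, seed = 3)
  expect_gte(same$p_value, 0.9)
  shifted <- bootstrap_trimmed_mean_test(x, x + 10 * stats::sd(x), seed = 3)
  expect_lt(shifted$p_value, 0.01)
  expect_warning(bootstrap_trimmed_mean_test(x, x, reps = 50, seed = 1),
                 "replicates")
  expect_error(bootstrap_trimmed_mean_test(x, x, trim = 0.4), "trim")
  expect_error(bootstrap_trimmed_mean_test(numeric(0), x), "Empty")

  # trim = 0 agrees with an ordinary bootstrap mean test oracle
  withr::with_seed(7, {
    a <- rnorm(30, 10, 2); b <- rnorm(30, 11, 2)
  })
  p_pkg <- bootstrap_trimmed_mean_test(a, b, reps = 4000, trim = 0, seed = 5)$p_value
  withr::with_seed(99, {
    boot <- replicate(4000, mean(sample(a, replace = TRUE)) -
                        mean(sample(b, replace = TRUE)))
  })
  p_oracle <- 2 * min((sum(boot <= 0) + 1) / 4001, (sum(boot >= 0) + 1) / 4001)
  expect_lt(abs(p_pkg - min(p_oracle, 1)), 0.05)
})
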