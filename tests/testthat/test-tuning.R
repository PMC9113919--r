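co15 <- ss_coords()

test_that("quadric fits interpolate exact quadrics and report adjusted R2", {
  q_true <- c(1.5, -0.3, 0.8, -0.6, 0.25, -0.45)
  amp <- with(co15, q_true[1] + q_true[2] * x + q_true[3] * t +
                q_true[4] * x^2 + q_true[5] * x * t + q_true[6] * t^2)
  fit <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = amp))
  expect_equal(unname(fit$coefficients), q_true, tolerance = 1e-8)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
  expect_error(fit_quadric(tibble::tibble(x = 1:8, t = 1:8, amplitude = rnorm(8))),
               "rank deficient")
  expect_error(fit_quadric(tibble::tibble(x = 1:5, t = 1:5, amplitude = 1:5)),
               "at least 7")
})

test_that("log-Gaussian surfaces give the expected cross-term structure", {
  sep <- exp(-(co15$x + 1)^2 / (2 * 0.8^2)) * exp(-(co15$t - 3.5)^2 / (2 * 0.8^2))
  f_sep <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = log(sep)))
  expect_lt(abs(f_sep$coefficients["q4"]), 1e-8)
  spd <- exp(-((co15$t - co15$x) - log2(24))^2 / 2)
  f_spd <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = log(spd)))
  expect_equal(unname(f_spd$coefficients["q4"]),
               unname(-2 * f_spd$coefficients["q5"]), tolerance = 1e-8)
})

test_that("Q index separates speed-tuned from separable surfaces", {
  sep <- exp(-(co15$x + 1)^2 / (2 * 0.8^2)) * exp(-(co15$t - 3.5)^2 / (2 * 0.8^2))
  f_sep <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = log(sep)))
  expect_equal(q_index(f_sep), -1, tolerance = 1e-6)
  spd <- exp(-((co15$t - co15$x) - log2(24))^2 / 2)
  f_spd <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = log(spd)))
  expect_equal(q_index(f_spd), 0, tolerance = 1e-6)
  # direct substitution and the undefined case
  f <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                  amplitude = -co15$t^2))
  expect_equal(q_index(f), -1, tolerance = 1e-8)
  f0 <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                   amplitude = -co15$x^2))
  expect_warning(qq <- q_index(f0), "undefined")
  expect_true(is.na(qq))
})

test_that("Q is invariant to joint axis rescaling and amplitude offsets", {
  set.seed(5)
  amp <- exp(-((co15$t - co15$x) - 4.5)^2 / 3 - 0.2 * (co15$x + 1)^2)
  f1 <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = amp))
  f2 <- fit_quadric(tibble::tibble(x = 3 * co15$x, t = 3 * co15$t, amplitude = amp))
  f3 <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = amp + 7))
  expect_equal(q_index(f1), q_index(f2), tolerance = 1e-9)
  expect_equal(q_index(f1), q_index(f3), tolerance = 1e-9)
})

test_that("axis angles satisfy the speed/scale anchor conventions", {
  # pure speed tuning: main axis aligned with speed
  f_u <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                    amplitude = -((co15$t - co15$x) - 4.5)^2))
  a_u <- suppressWarnings(axes_angles(f_u))
  expect_equal(a_u$phi, 0, tolerance = 1e-8)
  # spatial-frequency-only surface: theta = phi = -45
  f_x <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                    amplitude = -(co15$x + 1)^2))
  a_x <- suppressWarnings(axes_angles(f_x))
  expect_equal(a_x$theta, -45, tolerance = 1e-8)
  expect_equal(a_x$phi, -45, tolerance = 1e-8)
  # temporal-frequency-only surface: +45
  f_t <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                    amplitude = -(co15$t - 3.5)^2))
  a_t <- suppressWarnings(axes_angles(f_t))
  expect_equal(a_t$theta, 45, tolerance = 1e-8)
  expect_equal(a_t$phi, 45, tolerance = 1e-8)
})

test_that("the analytic iso-speed argmax locus matches brute-force search", {
  amp <- -(co15$x + 1)^2 - 0.3 * (co15$t - 3.5)^2 + 0.2 * co15$x * co15$t
  fit <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t, amplitude = amp))
  loc <- iso_speed_argmax(fit)
  slope <- stats::coef(stats::lm(w_max ~ u, loc))[2]
  expect_equal(unname(-atan(slope) * 180 / pi), axes_angles(fit)$theta,
               tolerance = 0.05)
  # saddle surfaces are flagged
  f_sad <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                      amplitude = co15$x^2 - 2 * co15$t^2))
  expect_warning(a_sad <- axes_angles(f_sad), "[Ss]addle")
  expect_true(a_sad$saddle)
})

test_that("per-window tuning tables carry coefficients, angles and Q", {
  set.seed(6)
  stats_tbl <- tidyr::crossing(condition_id = co15$id,
                               window = ofr_windows()$window) |>
    dplyr::left_join(co15, by = c(condition_id = "id")) |>
    dplyr::mutate(mu = exp(-((t - x) - log2(24))^2 / 2) * 8 + rnorm(75, 0, 0.01)) |>
    dplyr::select(-x, -t)
  # near-degenerate speed-tuned surfaces can flag as saddles under noise
  tw <- suppressWarnings(tuning_by_window(stats_tbl, ss_cat_mc$components))
  expect_equal(nrow(tw), 5)
  expect_true(all(c("q0", "q5", "adjusted_r2", "theta", "phi", "Q") %in% names(tw)))
  expect_true(all(abs(tw$Q) < 0.2))
  expect_true(all(tw$adjusted_r2 > 0.9))
  # broom-style accessors
  f <- fit_quadric(tibble::tibble(x = co15$x, t = co15$t,
                                  amplitude = log(exp(-((co15$t - co15$x))^2 / 2))))
  expect_equal(nrow(generics::tidy(f)), 6)
  expect_true("Q" %in% names(suppressWarnings(generics::glance(f))))
})
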