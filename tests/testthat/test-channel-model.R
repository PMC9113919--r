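test_that("the default bank tiles 722 channels inside the speed range", {
  expect_equal(nrow(ss_bank), 722)
  expect_gte(min(ss_bank$v), 1)
  expect_lte(max(ss_bank$v), 512)
  expect_true(all(ss_bank$weight > 0))
  expect_equal(max(ss_bank$weight), 1)
  expect_error(bank_spec(rho = 1), "rho")
})

test_that("channel weights peak at the reference spatial frequency", {
  pk <- weight_peak()
  expect_equal(pk$sf, 0.21, tolerance = 0.01 / 0.21)
  # dense-grid search oracle agrees with the analytic stationary point
  xs <- seq(-6, 3, by = 0.005)
  ts <- seq(-3, 7, by = 0.005)
  b <- default_weight_coefficients()
  best <- c(NA, -Inf)
  for (tt in ts) {
    w <- weight_polynomial(xs, tt, b)
    j <- which.max(w)
    if (w[j] > best[2]) best <- c(xs[j], w[j])
  }
  expect_equal(2^best[1], pk$sf, tolerance = 0.01)
})

test_that("channel responses follow the gain, weight and overlap structure", {
  spec <- ss_cat_dg$components[1, ]
  env <- dg_envelope(spec)
  m0 <- channel_response(ss_bank, env, g = 2, contrast = 0)
  expect_true(all(m0 == 0))
  # a grating at a channel's centre drives it by g^2 w c times the peak density
  bs <- attr(ss_bank, "spec")
  i <- which.min((ss_bank$x - log2(0.5))^2 + (ss_bank$t - log2(12))^2)
  spec_at <- spec
  spec_at$sf0 <- 2^ss_bank$x[i]; spec_at$tf0 <- 2^ss_bank$t[i]
  m <- channel_response(ss_bank, dg_envelope(spec_at), g = 3)
  peak <- 1 / (2 * pi * bs$sigma_x * bs$sigma_t * sqrt(1 - bs$rho^2))
  expect_equal(m[i], 3^2 * ss_bank$weight[i] * 0.6 * peak, tolerance = 1e-10)
  expect_error(channel_response(ss_bank, {
    e <- mc_envelope(ss_cat_mc$components[1, ]); e$mass <- e$mass * 2; e
  }), "normalized")
})

test_that("envelope-grid responses converge to the dense-grid oracle", {
  spec <- ss_cat_mc$components[1, ]
  m64 <- channel_response(ss_bank, mc_envelope(spec, n = 64))
  m256 <- channel_response(ss_bank, mc_envelope(spec, n = 256))
  act <- m256 > max(m256) * 0.01
  err64 <- max(abs(m64[act] - m256[act]) / m256[act])
  expect_lt(err64, 0.01)
  # error decreases with refinement (observed order >= 1 over 16 -> 128)
  merr <- sapply(c(16, 32, 128), function(n) {
    m <- channel_response(ss_bank, mc_envelope(spec, n = n))
    mean(abs(m[act] - m256[act]) / m256[act])
  })
  expect_true(all(diff(merr) < 0))
  expect_gt(merr[1] / merr[3], 8)
})

test_that("the interaction kernel is even, crossed, and null at the origin", {
  ip <- interaction_params()
  d <- interaction_kernel(ip)
  expect_equal(d(0, 0), 0, tolerance = 1e-14)
  set.seed(8)
  dx <- rnorm(20); dt <- rnorm(20)
  expect_equal(d(dx, dt), d(-dx, -dt), tolerance = 1e-12)
  # circular lobes with equal SDs cancel exactly everywhere
  ipc <- interaction_params(sigma_e1 = 0.5, sigma_e2 = 0.5,
                            sigma_i1 = 0.5, sigma_i2 = 0.5)
  dc <- interaction_kernel(ipc)
  expect_equal(max(abs(dc(dx, dt))), 0, tolerance = 1e-12)
  # reference parameters: inhibition along the scale diagonal at 3 octaves,
  # excitation along the speed diagonal
  expect_lt(d(-3 / sqrt(2), 3 / sqrt(2)), 0)
  expect_lt(d(-1 / sqrt(2), 1 / sqrt(2)), -0.5)
  expect_gt(d(1 / sqrt(2), 1 / sqrt(2)), 0.5)
})

test_that("interactions reduce to the feedforward drive when disabled", {
  ip0 <- interaction_params(sigma_e1 = 0.5, sigma_e2 = 0.5,
                            sigma_i1 = 0.5, sigma_i2 = 0.5)
  D0 <- interaction_matrix(ss_bank, ip0)
  m <- channel_response(ss_bank, dg_envelope(ss_cat_dg$components[1, ]), g = 2)
  expect_equal(apply_interactions(m, D0), m, tolerance = 1e-12)
  expect_identical(apply_interactions(m, NULL, mode = "off"), m)
  # single active channel: no self-interaction
  m1 <- numeric(nrow(ss_bank)); m1[100] <- 2
  D <- interaction_matrix(ss_bank, interaction_params())
  expect_equal(apply_interactions(m1, D), m1, tolerance = 1e-12)
  # two active channels: hand-computed two-term update
  m2 <- numeric(nrow(ss_bank)); m2[100] <- 2; m2[150] <- 3
  n2 <- apply_interactions(m2, D)
  expect_equal(n2[100], max(0, 2 * (1 + 3 * D[100, 150])), tolerance = 1e-12)
  expect_equal(n2[150], max(0, 3 * (1 + 2 * D[150, 100])), tolerance = 1e-12)
  # literal mode is the bare product
  nl <- apply_interactions(m2, D, mode = "literal")
  expect_equal(nl[100], 2 * (3 * D[100, 150]), tolerance = 1e-12)
})

test_that("speed likelihoods are unit-peak Gaussians combined by activity", {
  grid <- speed_grid()
  lp <- speed_logpsi(ss_bank, grid)
  # log psi at each channel's own speed is ~0 (grid-resolution limited)
  own <- vapply(seq_len(nrow(ss_bank)), function(i) {
    max(lp[i, ])
  }, 1)
  expect_true(all(own > -1e-3))
  # single active channel: likelihood peaks at its preferred speed
  n1 <- numeric(nrow(ss_bank)); n1[300] <- 5
  ll <- speed_loglik(n1, lp)
  expect_equal(as.numeric(grid)[which.max(ll)], log2(ss_bank$v[300]),
               tolerance = attr(grid, "dv"))
  # two equal channels at speeds a and b: maximum at the midpoint
  i1 <- which.min(abs(log2(ss_bank$v) - 3) + abs(ss_bank$x + 1))
  i2 <- which.min(abs(log2(ss_bank$v) - 5) + abs(ss_bank$x + 1))
  n2 <- numeric(nrow(ss_bank)); n2[c(i1, i2)] <- 1
  ll2 <- speed_loglik(n2, lp)
  mid <- (log2(ss_bank$v[i1]) + log2(ss_bank$v[i2])) / 2
  expect_equal(as.numeric(grid)[which.max(ll2)], mid, tolerance = attr(grid, "dv"))
})

test_that("posterior updates are Bayes-exact on the grid", {
  grid <- speed_grid()
  g <- as.numeric(grid); dv <- attr(grid, "dv")
  prior <- dnorm(g, 3, 0.8); prior <- prior / (sum(prior) * dv)
  # uniform likelihood leaves the prior untouched
  expect_equal(posterior_update(prior, rep(-2, length(g)), grid), prior,
               tolerance = 1e-12)
  # conjugate-Gaussian closed form
  ll <- -(g - 4.2)^2 / (2 * 0.5^2)
  post <- posterior_update(prior, ll, grid)
  w <- 1 / 0.8^2 + 1 / 0.5^2
  mu_th <- (3 / 0.8^2 + 4.2 / 0.5^2) / w
  sd_th <- sqrt(1 / w)
  mu_emp <- sum(post * g) * dv
  sd_emp <- sqrt(sum(post * g^2) * dv - mu_emp^2)
  expect_equal(mu_emp, mu_th, tolerance = 2 * dv)
  expect_equal(sd_emp, sd_th, tolerance = 2 * dv)
  # repeated identical likelihoods drive the mode to the likelihood mode
  p <- prior
  for (k in 1:40) p <- posterior_update(p, ll, grid)
  expect_equal(g[which.max(p)], 4.2, tolerance = 2 * dv)
  # disjoint support underflows with a diagnostic
  pr0 <- as.numeric(g > 9); pr0 <- pr0 / (sum(pr0) * dv)
  expect_error(posterior_update(pr0, -(g + 2)^2 * 1e4, grid), "underflow")
})

test_that("the window recursion sharpens toward the stimulus speed", {
  pp <- participant_params(g = 2)
  # zero contrast: posterior equals the prior at every window
  drv0 <- numeric(nrow(ss_bank))
  ps0 <- run_windows(drv0, ss_bank, pp)
  post0 <- attr(ps0, "matrix")
  expect_equal(post0[4, ], post0[1, ], tolerance = 1e-9)
  # normalization at every window
  grid <- attr(ps0, "grid")
  expect_true(all(abs(rowSums(post0) * attr(grid, "dv") - 1) < 1e-9))

  # flat weights, grating c1: mode moves monotonically toward log2(24)
  flat <- build_bank(b = setNames(rep(0, 6), paste0("b", 0:5)))
  drv <- channel_response(flat, dg_envelope(ss_cat_dg$components[1, ]))
  ps <- run_windows(drv, flat, pp)
  ms <- posterior_mean_speed(ps)
  gaps <- abs(ms$mode_log2_v - log2(24))
  expect_true(all(diff(gaps) < 1e-9))
  expect_lt(gaps[4], 0.1)
  # posterior variance non-increasing for a fixed unimodal likelihood
  expect_true(all(diff(ms$sd_log2_v) < 1e-9))
  # interactions change the sequence
  psi <- run_windows(drv, flat, pp, interaction_params())
  expect_false(isTRUE(all.equal(attr(ps, "matrix"), attr(psi, "matrix"))))
})

test_that("the kernel makes scale-aligned patterns sublinear in the decoder", {
  ids <- c("c8", "c1", "c12", "c10", "c14")
  drv <- sapply(ids, function(i) {
    channel_response(ss_bank, mc_envelope(
      ss_cat_mc$components[ss_cat_mc$components$id == i, ]))
  })
  pn <- pattern_nonlinearity(drv, list(d = c("c8", "c1", "c12"),
                                       i = c("c10", "c1", "c14")),
                             ss_bank, participant_params(g = 2))
  expect_lt(pn$cross_interaction[pn$pattern == "d"], 0)
  expect_gt(pn$cross_interaction[pn$pattern == "i"], 0)
  expect_lt(pn$rnl_model[pn$pattern == "d"], 0.95)
  expect_gt(pn$rnl_model[pn$pattern == "i"], 0.98)
})
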