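# shared fixtures, built in code at load time
ss_cat_mc <- stimulus_catalog("MC")
ss_cat_dg <- stimulus_catalog("DG")
ss_bank <- build_bank()

# coordinates of the 15 components in octaves
ss_coords <- function(cat = ss_cat_mc) {
  tibble::tibble(id = cat$components$id,
                 x = log2(cat$components$sf0),
                 t = log2(cat$components$tf0))
}

# white-noise trial tibble around a mean trace (1 kHz, 0..399 ms)
ss_noise_trials <- function(n_trials, mean_fun = function(t) rep(0, length(t)),
                            sd = 1.5, prefix = "tr", seed = 1) {
  t <- 0:399
  mu <- mean_fun(t)
  withr::with_seed(seed, {
    purrr::list_rbind(purrr::map(seq_len(n_trials), function(i) {
      tibble::tibble(trial_id = sprintf("%s_%03d", prefix, i), time_ms = t,
                     velocity = mu + stats::rnorm(length(t), 0, sd))
    }))
  })
}
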