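# Desk-scale movie synthesis. Motion clouds are built by direct summation of
# random-phase drifting Gabor elements whose characteristics are sampled from
# the spectral envelope distributions; gratings evaluate the sinusoid
# directly. Pixel values are in luminance-contrast units (zero mean).

#' Movie synthesis configuration
#'
#' @param n_elements Number of Gabor elements summed for a motion cloud.
#' @param frame_size Pixels per (square) frame side.
#' @param duration Number of frames.
#' @param pixel_pitch Degrees of visual angle per pixel.
#' @param frame_rate Frames per second (Hz).
#' @param seed Integer seed; the same seed reproduces the movie bit for bit.
#' @param env_cycles Gaussian envelope size of each Gabor element, in carrier
#'   cycles (sets the per-element spectral spread).
#' @return List of class `movie_config`.
#' @export
movie_config <- function(n_elements = 200, frame_size = 32, duration = 20,
                         pixel_pitch = 0.25, frame_rate = 100, seed = 1,
                         env_cycles = 1.5) {
  cfg <- list(n_elements = n_elements, frame_size = frame_size,
              duration = duration, pixel_pitch = pixel_pitch,
              frame_rate = frame_rate, seed = seed, env_cycles = env_cycles)
  if (any(unlist(cfg[1:5]) <= 0)) abort("All movie_config dimensions must be positive.")
  structure(cfg, class = "movie_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

grating_movie <- function(spec, cfg, phi0) {
  px <- (seq_len(cfg$frame_size) - 1) * cfg$pixel_pitch
  tau <- (seq_len(cfg$duration) - 1) / cfg$frame_rate
  # vertical orientation: carrier varies along x and drifts horizontally
  frames <- array(0, c(cfg$duration, cfg$frame_size, cfg$frame_size))
  for (k in seq_along(tau)) {
    row <- sin(2 * pi * (spec$sf0 * px + spec$tf0 * tau[k]) + phi0)
    frames[k, , ] <- matrix(row, cfg$frame_size, cfg$frame_size, byrow = FALSE)
  }
  frames
}

cloud_movie <- function(spec, cfg) {
  n <- cfg$n_elements
  s_sf <- fwhm_to_sigma(spec$b_sf)
  s_v <- fwhm_to_sigma(spec$b_v)
  sf_i <- 2^rnorm(n, log2(spec$sf0), s_sf)
  v_i <- 2^rnorm(n, log2(spec$v0), s_v)
  tf_i <- sf_i * v_i
  # orientation spread about vertical; wavevector direction = theta - 90
  ang <- (rnorm(n, spec$theta0, spec$dtheta) - 90) * pi / 180
  phs <- runif(n, 0, 2 * pi)
  px <- (seq_len(cfg$frame_size) - 1) * cfg$pixel_pitch
  pos_x <- runif(n, min(px), max(px))
  pos_y <- runif(n, min(px), max(px))
  tau <- (seq_len(cfg$duration) - 1) / cfg$frame_rate
  xg <- matrix(px, cfg$frame_size, cfg$frame_size)
  yg <- t(xg)
  frames <- array(0, c(cfg$duration, cfg$frame_size, cfg$frame_size))
  for (i in seq_len(n)) {
    sig <- cfg$env_cycles / sf_i[i]
    # each element is normalized to equal energy so the realized spectrum
    # follows the sampled envelope distribution
    envl <- exp(-((xg - pos_x[i])^2 + (yg - pos_y[i])^2) / (2 * sig^2))
    envl <- envl / sqrt(mean(envl^2))
    sp <- 2 * pi * sf_i[i] * (xg * cos(ang[i]) + yg * sin(ang[i])) + phs[i]
    for (k in seq_along(tau)) {
      frames[k, , ] <- frames[k, , ] + envl * cos(sp + 2 * pi * tf_i[i] * tau[k])
    }
  }
  frames
}

#' Synthesize a stimulus movie
#'
#' Builds a short movie for a component (motion cloud or drifting grating)
#' or for a pattern (scaled sum of its component movies). Motion clouds sum
#' `n_elements` drifting Gabor elements with characteristics drawn from the
#' component's envelope distributions and uniform random phases; gratings
#' are the analytic drifting sinusoid. The result is rescaled so its
#' root-mean-square contrast equals the catalog contrast (0.60 by default).
#'
#' @param spec A component or pattern row from [stimulus_catalog()].
#' @param cfg A [movie_config()].
#' @param components Component tibble, required when `spec` is a pattern.
#' @return Array `duration x frame_size x frame_size` of class `ss_movie`
#'   (luminance contrast units, zero mean carrier).
#' @examples
#' cat15 <- stimulus_catalog("DG")
#' mov <- synthesize_movie(cat15$components[1, ], movie_config(seed = 7))
#' sqrt(mean(mov^2))
#' @export
synthesize_movie <- function(spec, cfg = movie_config(), components = NULL) {
  stopifnot(nrow(spec) == 1)
  is_pattern <- "component_ids" %in% names(spec)
  frames <- with_seed(cfg$seed, {
    if (is_pattern) {
      if (is.null(components)) abort("Pattern synthesis needs the component tibble.")
      ids <- spec$component_ids[[1]]
      members <- components[match(ids, components$id), ]
      movs <- map(seq_len(nrow(members)), function(i) {
        m <- members[i, ]
        if (m$stimulus_type == "MC") cloud_movie(m, cfg)
        else grating_movie(m, cfg, phi0 = runif(1, 0, 2 * pi))
      })
      Reduce(`+`, movs)
    } else if (spec$stimulus_type == "MC") {
      if (cfg$n_elements < 20) {
        warn("Very few Gabor elements; the movie will approximate the envelope poorly.")
      }
      cloud_movie(spec, cfg)
    } else {
      grating_movie(spec, cfg, phi0 = runif(1, 0, 2 * pi))
    }
  })
  frames <- frames - mean(frames)
  frames <- frames * (spec$contrast / sqrt(mean(frames^2)))
  structure(frames, class = c("ss_movie", "array"),
            id = spec$id, pixel_pitch = cfg$pixel_pitch,
            frame_rate = cfg$frame_rate)
}

#' Fraction of movie power inside an octave box around a centre frequency
#'
#' Computes the 3-D power spectrum (Hann-windowed in time and space to
#' limit rectangular-window leakage at desk-scale frame sizes and
#' durations) and reports the fraction of total non-DC power
#' inside the envelope box: radial spatial frequency within `octaves` of
#' `sf0` and speed (temporal over spatial frequency) within `octaves` of
#' `tf0/sf0`. Spatial frequency and speed are the axes along which the
#' motion-cloud envelope is parameterized (1-octave FWHM each), so the box
#' is aligned with the oriented ellipse the stimulus is meant to occupy.
#'
#' @param movie An `ss_movie`.
#' @param sf0,tf0 Centre spatial (cyc/deg) and temporal (Hz) frequency.
#' @param octaves Half-width of the box in octaves (default 1: a 2-octave box).
#' @return Fraction in \[0, 1\].
#' @export
movie_power_concentration <- function(movie, sf0, tf0, octaves = 1) {
  d <- dim(movie)
  pitch <- attr(movie, "pixel_pitch"); rate <- attr(movie, "frame_rate")
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  w3 <- outer(hann(d[1]), as.vector(outer(hann(d[2]), hann(d[3]))))
  arr <- array(movie, d) * array(w3, d)
  arr <- arr - mean(arr)
  pw <- abs(fft(arr))^2
  fr <- function(n, step) {
    k <- seq_len(n) - 1
    k[k > n / 2] <- k[k > n / 2] - n
    k / (n * step)
  }
  ft <- fr(d[1], 1 / rate)
  fx <- fr(d[2], pitch)
  fy <- fr(d[3], pitch)
  sfr <- pmax(sqrt(outer(fx^2, fy^2, `+`)), 1e-12)
  v0 <- tf0 / sf0
  inside_sp <- abs(log2(sfr / sf0)) <= octaves
  # per (ft, sf) pair: speed of the bin
  spd <- outer(pmax(abs(ft), 1e-12), as.vector(sfr), `/`)
  sel <- sweep(abs(log2(spd / v0)) <= octaves, 2, as.vector(inside_sp), `&`)
  sum(pw[array(sel, d)]) / sum(pw)
}
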