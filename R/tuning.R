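# Quadric tuning surfaces over the log-frequency plane, the speed/scale
# axis angles Theta and Phi, and the separability index Q.

#' Fit a quadric surface to response amplitudes
#'
#' Ordinary least squares fit of
#' `R(x, t) = q0 + q1 x + q2 t + q3 x^2 + q4 x t + q5 t^2`
#' with `x = log2 sf` and `t = log2 tf`, the assumption-free description of
#' a spatiotemporal tuning surface through windowed response amplitudes.
#'
#' @param data Tibble with columns `x` (log2 sf), `t` (log2 tf) and
#'   `amplitude` (mean eye velocity, deg/s); at least 7 points of full rank.
#' @return Object of class `quadric_fit`: coefficients `q0..q5`,
#'   `adjusted_r2`, residuals and the data.
#' @examples
#' co <- stimulus_catalog()$components
#' pts <- tibble::tibble(x = log2(co$sf0), t = log2(co$tf0),
#'                       amplitude = exp(-((log2(co$tf0 / co$sf0) - log2(24))^2) / 2))
#' fit_quadric(pts)
#' @export
fit_quadric <- function(data) {
  stopifnot(all(c("x", "t", "amplitude") %in% names(data)))
  if (nrow(data) < 7) abort("Quadric fit needs at least 7 points.")
  X <- with(data, cbind(1, x, t, x^2, x * t, t^2))
  qr_x <- qr(X)
  if (qr_x$rank < 6) {
    abort("Degenerate point geometry: the quadric design matrix is rank deficient (points may be collinear or too few distinct frequencies).")
  }
  beta <- qr.coef(qr_x, data$amplitude)
  fitted <- as.vector(X %*% beta)
  rss <- sum((data$amplitude - fitted)^2)
  tss <- sum((data$amplitude - mean(data$amplitude))^2)
  n <- nrow(data)
  adj <- if (tss > 0 && n > 6) 1 - (rss / (n - 6)) / (tss / (n - 1)) else NA_real_
  structure(list(coefficients = setNames(as.numeric(beta), paste0("q", 0:5)),
                 adjusted_r2 = adj, fitted = fitted,
                 residuals = data$amplitude - fitted, data = data),
            class = "quadric_fit")
}

#' @export
print.quadric_fit <- function(x, ...) {
  cat("<quadric_fit> adj R^2 =", round(x$adjusted_r2, 4), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Speed-tuning separability index Q
#'
#' `Q = -(1 + q4 / (2 q5))` from the cross and quadratic-temporal
#' coefficients of a quadric tuning surface. `Q = 0` indicates speed-tuned
#' (inseparable) frequency coding; `Q = -1` indicates independent (separable)
#' spatial and temporal frequency tuning. Q is invariant to rescaling both
#' frequency axes together and to adding a constant to the amplitudes.
#'
#' @param fit A `quadric_fit`.
#' @param tol `|q5|` below this yields `NA` with a warning (undefined Q).
#' @return Scalar Q (unitless), or `NA` when undefined.
#' @export
q_index <- function(fit, tol = 1e-10) {
  q <- fit$coefficients
  if (abs(q["q5"]) < tol) {
    warn("q5 is ~0; the Q index is undefined for this surface.")
    return(NA_real_)
  }
  unname(-(1 + q["q4"] / (2 * q["q5"])))
}

# quadric coefficients rotated to speed-scale coordinates
# u = (t - x)/sqrt(2) (log speed), w = (t + x)/sqrt(2) (log scale)
uw_form <- function(q) {
  A <- matrix(c(-1, 1, 1, 1), 2, 2) / sqrt(2) # rows: u, w in terms of (x, t)
  H <- matrix(c(2 * q["q3"], q["q4"], q["q4"], 2 * q["q5"]), 2, 2)
  Huw <- A %*% H %*% t(A)
  luw <- A %*% c(q["q1"], q["q2"])
  list(H = Huw, l = as.vector(luw))
}

#' Speed/scale axis angles of a quadric tuning surface
#'
#' In speed-scale coordinates `u = (t - x)/sqrt(2)`, `w = (t + x)/sqrt(2)`:
#' `theta` is the angle of the max speed-scale locus - the straight line of
#' scales maximizing the surface along each iso-speed section - and `phi`
#' the angle of the dominant curvature axis of the surface. Angles are in
#' degrees in (-90, 90], measured from the speed axis with the convention
#' that a surface tuned purely to speed gives `phi = 0`, one tuned purely to
#' spatial frequency gives `theta = phi = -45`, and one tuned purely to
#' temporal frequency gives `+45`.
#'
#' @param fit A `quadric_fit`.
#' @return Tibble with `theta`, `phi` (degrees) and `saddle` (`TRUE` when
#'   the Hessian is saddle-shaped, in which case the angles describe the
#'   saddle's axes).
#' @export
axes_angles <- function(fit) {
  q <- fit$coefficients
  f <- uw_form(q)
  ev <- eigen(f$H, symmetric = TRUE)
  tol <- 1e-9 * max(abs(ev$values), 1e-300)
  saddle <- max(ev$values) > tol && min(ev$values) < -tol
  r4 <- f$H[1, 2]; r5 <- f$H[2, 2] / 2
  if (abs(r5) < 1e-12) {
    warn("No curvature along the scale direction; theta is undefined.")
    theta <- NA_real_
  } else {
    # iso-speed argmax: w*(u) = -(l_w + r4 u) / (2 r5), slope -r4/(2 r5);
    # angles are clockwise-positive from the speed axis
    theta <- fold_pm90(-atan(-r4 / (2 * r5)) * 180 / pi)
  }
  dom <- ev$vectors[, which.max(abs(ev$values))]
  phi <- fold_pm90(atan2(dom[2], dom[1]) * 180 / pi)
  if (saddle) {
    warn("Saddle-shaped quadric; axis angles refer to the saddle axes.")
  }
  tibble(theta = theta, phi = phi, saddle = saddle)
}

#' Per-speed argmax locus of a quadric surface
#'
#' Brute-force counterpart of the analytic locus used by [axes_angles()]:
#' for each iso-speed coordinate `u`, finds the scale `w` maximizing the
#' surface over a dense grid. For a quadric the locus is a straight line.
#'
#' @param fit A `quadric_fit`.
#' @param u Speed coordinates at which to evaluate.
#' @param w Dense grid of scale coordinates searched per speed.
#' @return Tibble `u`, `w_max`.
#' @export
iso_speed_argmax <- function(fit, u = seq(-2, 2, length.out = 9),
                             w = seq(-20, 20, length.out = 8001)) {
  f <- uw_form(fit$coefficients)
  vals <- map_dbl(u, function(ui) {
    r <- f$l[1] * ui + f$l[2] * w + 0.5 * f$H[1, 1] * ui^2 +
      f$H[1, 2] * ui * w + 0.5 * f$H[2, 2] * w^2
    w[which.max(r)]
  })
  tibble(u = u, w_max = vals)
}

#' Fit tuning surfaces for every analysis window
#'
#' Convenience wrapper: joins window statistics with component coordinates,
#' fits a quadric per window, and returns the per-window coefficient table
#' with angles and Q.
#'
#' @param stats Window statistics from [window_stats()] for the 15
#'   components (condition ids matching catalog component ids).
#' @param components Component tibble from [stimulus_catalog()].
#' @return Tibble: one row per window with `q0..q5`, `adjusted_r2`, `theta`,
#'   `phi`, `Q`.
#' @export
tuning_by_window <- function(stats, components) {
  co <- component_coords(components)
  stats |>
    inner_join(co, by = c(condition_id = "id")) |>
    group_by(.data$window) |>
    group_modify(function(d, key) {
      fit <- fit_quadric(tibble(x = d$x, t = d$t, amplitude = d$mu))
      ang <- axes_angles(fit)
      tibble(!!!as.list(fit$coefficients),
             adjusted_r2 = fit$adjusted_r2,
             theta = ang$theta, phi = ang$phi,
             Q = q_index(fit))
    }) |>
    ungroup()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.quadric_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.quadric_fit <- function(x, ...) {
  ang <- suppressWarnings(axes_angles(x))
  tibble(adjusted_r2 = x$adjusted_r2, Q = suppressWarnings(q_index(x)),
         theta = ang$theta, phi = ang$phi, saddle = ang$saddle,
         nobs = nrow(x$data))
}
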