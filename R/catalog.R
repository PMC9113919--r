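#' Load the packaged stimulus catalog
#'
#' The study design uses 15 single motion components (available both as
#' broadband motion clouds, MC, and as drifting gratings, DG) tiling an
#' oblique rectangle of the log spatiotemporal frequency plane, plus 9
#' pattern stimuli built by superimposing 2-3 of those components. The
#' catalog ships with the package as plain CSV and carries, for every
#' component, its speed `v0` (deg/s), spatial frequency `sf0` (cyc/deg),
#' temporal frequency `tf0` (Hz) and the printed relative geometry
#' (distance from the reference component c1 in grid units, polar angle in
#' degrees); for every pattern, its component list, mean speed, end-to-end
#' span and orientation.
#'
#' Every MC shares the fixed distribution parameters: vertical orientation
#' (`theta0 = 90` degrees), orientation spread `dtheta = 15` degrees,
#' spatial-frequency and speed bandwidths of 1 octave FWHM, and an RMS
#' contrast of 0.60. A DG uses the same centre frequencies with zero-width
#' distributions (a point in frequency space).
#'
#' @param stimulus_type `"MC"` or `"DG"`; attached to the component rows so
#'   downstream envelope/model code picks the broadband or the point path.
#' @return A list with class `stimulus_catalog`: `components` (tibble, 15
#'   rows) and `patterns` (tibble, 9 rows).
#' @examples
#' cat15 <- stimulus_catalog()
#' cat15$components[1, ]
#' @export
stimulus_catalog <- function(stimulus_type = c("MC", "DG")) {
  stimulus_type <- match.arg(stimulus_type)
  comp_path <- system.file("extdata", "components.csv", package = "speedscale")
  pat_path <- system.file("extdata", "patterns.csv", package = "speedscale")
  if (comp_path == "" || pat_path == "") {
    abort("Packaged stimulus catalog not found; the installation is corrupted.")
  }
  components <- as_tibble(read.csv(comp_path, stringsAsFactors = FALSE))
  patterns <- as_tibble(read.csv(pat_path, stringsAsFactors = FALSE))

  if (nrow(components) != 15 || nrow(patterns) != 9) {
    abort(sprintf(
      "Corrupted stimulus catalog: expected 15 components and 9 patterns, found %d and %d.",
      nrow(components), nrow(patterns)
    ))
  }
  if (any(components$sf0 <= 0) || any(components$tf0 <= 0)) {
    abort("Corrupted stimulus catalog: non-positive frequencies.")
  }
  # v0 = tf0 / sf0 up to printed rounding
  if (any(abs(components$v0 - components$tf0 / components$sf0) /
            components$v0 > 0.01)) {
    abort("Corrupted stimulus catalog: speeds inconsistent with tf0/sf0.")
  }

  zero_u <- stimulus_type == "DG"
  components <- components |>
    mutate(
      stimulus_type = .env$stimulus_type,
      theta0 = 90,
      dtheta = if (zero_u) 0 else 15,
      b_sf = if (zero_u) 0 else 1,
      b_v = if (zero_u) 0 else 1,
      contrast = 0.60
    )

  patterns <- patterns |>
    mutate(component_ids = strsplit(.data$component_ids, ";", fixed = TRUE),
           contrast = 0.60)
  bad <- patterns |>
    filter(!map_dbl(.data$component_ids, length) %in% c(2, 3) |
             !map_dbl(.data$component_ids,
                      ~ all(.x %in% components$id)) == 1)
  if (nrow(bad) > 0) {
    abort(paste0("Corrupted stimulus catalog: unresolved pattern components in ",
                 paste(bad$id, collapse = ", ")))
  }

  structure(list(components = components, patterns = patterns),
            class = "stimulus_catalog")
}

#' @export
print.stimulus_catalog <- function(x, ...) {
  cat("<stimulus_catalog>", nrow(x$components), "components (",
      x$components$stimulus_type[1], "),", nrow(x$patterns), "patterns\n")
  print(x$components[, c("id", "v0", "sf0", "tf0", "distance", "angle")])
  invisible(x)
}

# log-frequency coordinates of components; base only rescales both axes
component_coords <- function(components, log_base = 2) {
  tibble(
    id = components$id,
    x = log(components$sf0, base = log_base),
    t = log(components$tf0, base = log_base)
  )
}

#' Relative geometry of components in the log-frequency plane
#'
#' Computes, for every component, the Euclidean distance and polar angle of
#' its (log sf, log tf) coordinates relative to a reference component. The
#' distance is expressed in grid units: one grid unit is the length of the
#' step between the two components named in `unit_pair` (by construction the
#' nearest-ring spacing of the stimulus lattice, printed as 1.00 in the
#' catalog). Because both axes use the same log base, both the angle and
#' the normalized distance are invariant to the choice of base.
#'
#' @param components Component tibble (see [stimulus_catalog()]).
#' @param reference Id of the reference component (default `"c1"`).
#' @param unit_pair Character vector of two ids whose separation defines one
#'   grid unit; if either is absent the raw log distance (in `log_base`
#'   units) is used.
#' @param log_base Log base for the coordinates (default 2, octaves).
#' @return A tibble with `id`, `distance` (grid units), `angle` (degrees in
#'   (-180, 180]) and `angle_undefined` (`TRUE` on the reference row, where
#'   the angle is reported as 0 by convention).
#' @examples
#' stimulus_catalog()$components |> relative_geometry()
#' @export
relative_geometry <- function(components, reference = "c1",
                              unit_pair = c("c1", "c5"), log_base = 2) {
  co <- component_coords(components, log_base)
  if (!reference %in% co$id) abort(sprintf("Reference '%s' not in catalog.", reference))
  ref <- co[co$id == reference, ]
  dx <- co$x - ref$x
  dt <- co$t - ref$t
  unit <- 1
  if (all(unit_pair %in% co$id)) {
    p1 <- co[co$id == unit_pair[1], ]
    p2 <- co[co$id == unit_pair[2], ]
    unit <- sqrt((p1$x - p2$x)^2 + (p1$t - p2$t)^2)
  }
  undef <- dx == 0 & dt == 0
  tibble(
    id = co$id,
    distance = sqrt(dx^2 + dt^2) / unit,
    angle = ifelse(undef, 0, fold_pm180(atan2(dt, dx) * 180 / pi)),
    angle_undefined = undef
  )
}

#' Geometry of pattern stimuli
#'
#' For every pattern, recomputes from its components' frequency coordinates:
#' the mean speed (the central component speed: the median over the
#' components, which equals the pairwise arithmetic mean for two-component
#' patterns; this is the value the catalog prints), the
#' end-to-end span between the two most distant components (grid units, same
#' normalization as [relative_geometry()]) and the orientation of the
#' component line in the log-frequency plane, folded into \[0, 180) degrees.
#' Orientation is the principal axis of the component coordinates, so a
#' non-collinear triplet gets its best-fit line together with a warning when
#' the RMS perpendicular residual exceeds `collinear_tol`.
#'
#' @param patterns Pattern tibble (see [stimulus_catalog()]).
#' @param components Component tibble the patterns refer to.
#' @param unit_pair,log_base Passed to the same normalization as
#'   [relative_geometry()].
#' @param collinear_tol RMS perpendicular residual (grid units) above which a
#'   non-collinear warning is emitted.
#' @return Tibble with `id`, `mean_speed`, `span`, `orientation`, `residual`.
#' @examples
#' cat15 <- stimulus_catalog()
#' pattern_geometry(cat15$patterns, cat15$components)
#' @export
pattern_geometry <- function(patterns, components, unit_pair = c("c1", "c5"),
                             log_base = 2, collinear_tol = 0.05) {
  co <- component_coords(components, log_base)
  unit <- 1
  if (all(unit_pair %in% co$id)) {
    p1 <- co[co$id == unit_pair[1], ]
    p2 <- co[co$id == unit_pair[2], ]
    unit <- sqrt((p1$x - p2$x)^2 + (p1$t - p2$t)^2)
  }
  one <- function(ids, pid) {
    idx <- match(ids, co$id)
    if (anyNA(idx)) abort(sprintf("Pattern '%s' references unknown components.", pid))
    xs <- co$x[idx]; ts <- co$t[idx]
    v <- components$v0[match(ids, components$id)]
    # end-to-end distance between the two extreme components
    dd <- as.matrix(stats::dist(cbind(xs, ts)))
    span <- max(dd) / unit
    if (span == 0) {
      return(tibble(id = pid, mean_speed = stats::median(v), span = 0,
                    orientation = 0, residual = 0))
    }
    # principal axis of the centred coordinates
    m <- cbind(xs - mean(xs), ts - mean(ts))
    sv <- svd(m)
    dirv <- sv$v[, 1]
    orientation <- fold_0180(atan2(dirv[2], dirv[1]) * 180 / pi)
    resid <- sqrt(mean((m %*% sv$v[, 2])^2)) / unit
    if (resid > collinear_tol) {
      warn(sprintf("Pattern '%s': components deviate from a line (RMS residual %.3f grid units); reporting best-fit orientation.",
                   pid, resid))
    }
    tibble(id = pid, mean_speed = stats::median(v), span = span,
           orientation = orientation, residual = resid)
  }
  list_rbind(map2(patterns$component_ids, patterns$id, one))
}
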