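# shared small helpers

#' Convert a full-width-at-half-maximum bandwidth to a Gaussian SD
#'
#' Motion-cloud bandwidths are specified as FWHM in octaves; internally the
#' spectral envelopes are Gaussians in log2 frequency, so
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm Full width at half maximum (octaves).
#' @return Gaussian standard deviation in the same units.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# fold an angle in degrees into (-180, 180]
fold_pm180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

# fold an orientation in degrees into [0, 180)
fold_0180 <- function(a) {
  a <- a %% 180
  ifelse(a < 0, a + 180, a)
}

# fold an axis angle in degrees into (-90, 90]
fold_pm90 <- function(a) {
  a <- fold_pm180(a)
  a <- ifelse(a > 90, a - 180, a)
  ifelse(a <= -90, a + 180, a)
}

# full width at half maximum of a sampled curve, by linear interpolation of
# the two half-height crossings around the peak
sampled_fwhm <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  imax <- which.max(y)
  half <- y[imax] / 2
  cross <- function(idx) {
    # idx: indices ordered moving away from the peak; find first drop below half
    below <- which(y[idx] < half)
    if (length(below) == 0) return(NA_real_)
    j <- below[1]
    i1 <- idx[j - 1]; i2 <- idx[j]
    x[i1] + (x[i2] - x[i1]) * (half - y[i1]) / (y[i2] - y[i1])
  }
  left <- cross(rev(seq_len(imax)))
  right <- cross(seq(imax, length(x)))
  right - left
}
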