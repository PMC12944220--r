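# Flat-interface refraction geometry shared by the simulator (forward
# distortion) and the volume module (correction).
#
# A ray leaving the camera at incidence angle theta to the water-surface
# normal refracts at the interface (Snell's law, index n_w ~ 1.33). A point
# at true camera distance d_real then appears at
#   d_app = d_real * sqrt(n_w^2 - sin^2 theta) / n_w,
# so the correction is d_real = d_app * n_w / sqrt(n_w^2 - sin^2 theta).
# Volume, a cubic quantity, scales by the cube of the depth factor.

#' Refraction depth factor d_real / d_app
#'
#' @param theta incidence angle in radians, in \code{[0, pi/2)}.
#' @param n_w refractive index of water (default 1.33).
#' @param approx_as_printed use the first-order small-angle expansion
#'   \code{n_w * (1 + sin^2(theta) / (2 n_w^2))} instead of the exact form.
#'   Note the expansion carries an overall factor \code{n_w} and therefore
#'   does not equal 1 at normal incidence; it is provided for comparison
#'   only.
#' @return dimensionless factor, 1 at \code{theta = 0} in the exact form.
#' @export
refract_depth_factor <- function(theta, n_w = 1.33, approx_as_printed = FALSE) {
  if (any(theta < 0) || any(theta >= pi / 2)) stop("theta must be in [0, pi/2)")
  if (n_w <= 1) stop("n_w must exceed 1")
  if (approx_as_printed) {
    n_w * (1 + sin(theta)^2 / (2 * n_w^2))
  } else {
    n_w / sqrt(n_w^2 - sin(theta)^2)
  }
}

#' Apparent depth under flat-surface refraction
#'
#' Forward distortion used by the simulator: the depth a camera registers
#' for a point at true distance \code{true_depth} seen at incidence angle
#' \code{theta}. Exact inverse of \code{\link{refraction_correct}}'s depth
#' factor, so correction recovers the input.
#'
#' @param true_depth true metric depth (meters); scalar, vector or matrix.
#' @param theta incidence angle in radians, \code{[0, pi/2)}; recycled
#'   against \code{true_depth}.
#' @param n_w water refractive index, > 1.
#' @return apparent depth, same shape as \code{true_depth}.
#' @export
apparent_depth <- function(true_depth, theta, n_w = 1.33) {
  true_depth / refract_depth_factor(theta, n_w)
}

#' Refraction-corrected volume
#'
#' Scales a preliminary volume estimate by the cubed depth factor
#' \code{(d_real/d_app)^3} at the fish's incidence angle.
#'
#' @param V_pre preliminary volume (cm^3), vectorized.
#' @param theta incidence angle in radians, \code{[0, pi/2)}.
#' @param n_w water refractive index.
#' @param approx_as_printed see \code{\link{refract_depth_factor}}.
#' @return list with \code{V} (corrected volume, cm^3), \code{factor}
#'   (the depth factor d_real/d_app) and \code{volume_factor} (its cube).
#' @export
refraction_correct <- function(V_pre, theta, n_w = 1.33,
                               approx_as_printed = FALSE) {
  f <- refract_depth_factor(theta, n_w, approx_as_printed)
  list(V = V_pre * f^3, factor = f, volume_factor = f^3)
}

#' Recover true depth from apparent depth
#'
#' @param d_app apparent depth (meters).
#' @inheritParams refract_depth_factor
#' @return true depth (meters).
#' @export
correct_depth <- function(d_app, theta, n_w = 1.33) {
  d_app * refract_depth_factor(theta, n_w)
}
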