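#' Hertzian two-plate compression force of an elastic sphere
#'
#' Forward model of the antero-posterior plate-compression test used to
#' calibrate the fetal head's Young's modulus: a sphere of radius R between
#' two rigid plates, each contact indenting delta/2, with Hertz contact
#' force \eqn{F = \tfrac{4}{3} E^* \sqrt{R} (\delta/2)^{3/2}},
#' \eqn{E^* = E / (1 - \nu^2)}. With E in MPa and lengths in mm the force
#' comes out in N.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param R sphere radius (mm).
#' @param delta total plate-to-plate deflection (mm), 0 <= delta < R
#'   (vectorised).
#' @return Force (N).
#' @examples
#' plate_compression_force(E = 1.1, nu = 0.25, R = 45, delta = 5)  # 41.48 N
#' @export
plate_compression_force <- function(E, nu, R = 45, delta) {
  stopifnot(E > 0, nu > -1, nu < 0.5, R > 0)
  if (any(delta < 0) || any(delta >= R)) {
    stop("contact-model validity requires 0 <= delta < R")
  }
  Estar <- E / (1 - nu^2)
  (4 / 3) * Estar * sqrt(R) * (delta / 2)^(3 / 2)
}

#' Compression force-deflection curve container
#'
#' @param deflection deflections (mm), non-negative, strictly increasing.
#' @param force forces (N), non-negative.
#' @param radius sphere radius used (mm).
#' @param noise_cv multiplicative noise level used to generate the curve
#'   (0 for measured/noiseless data).
#' @param seed RNG seed used (NA if none).
#' @return data.frame of class \code{"compression_curve"}.
#' @export
compression_curve <- function(deflection, force, radius = 45,
                              noise_cv = 0, seed = NA) {
  stopifnot(length(deflection) == length(force),
            all(deflection >= 0), all(diff(deflection) > 0),
            all(force >= 0))
  structure(data.frame(deflection = deflection, force = force),
            radius = radius, noise_cv = noise_cv, seed = seed,
            class = c("compression_curve", "data.frame"))
}

#' Calibrate the Young's modulus from a compression curve
#'
#' Least-squares fit of the Hertz forward model to a force-deflection
#' curve with the Poisson's ratio and radius held fixed (only E is
#' optimized). Because the Hertz force is exactly linear in E, the
#' minimizer of \eqn{\sum (F_{model} - F_{data})^2} is the linear
#' least-squares solution, computed via [stats::lm()] on the unit-modulus
#' model curve; the fit's residual norm and relative standard error are
#' reported.
#'
#' @param curve a [compression_curve()] (>= 3 points, strictly increasing
#'   deflections).
#' @param nu fixed Poisson's ratio (default 0.25).
#' @param R fixed sphere radius (mm); defaults to the curve's recorded
#'   radius.
#' @return List of class \code{"head_calibration"}: \code{E} (MPa),
#'   \code{residual_norm} (N), \code{relative_se}, \code{n}, \code{fit}.
#' @export
calibrate_young_modulus <- function(curve, nu = 0.25, R = NULL) {
  stopifnot(inherits(curve, "compression_curve"))
  if (nrow(curve) < 3) {
    stop("data error: calibration needs at least 3 curve points")
  }
  if (is.null(R)) R <- attr(curve, "radius")
  f_unit <- plate_compression_force(E = 1, nu = nu, R = R,
                                    delta = curve$deflection)
  fit <- stats::lm(curve$force ~ 0 + f_unit)
  E <- unname(stats::coef(fit)[1])
  if (!is.finite(E) || E <= 0) {
    stop("optimization error: non-positive or non-finite modulus estimate")
  }
  # standard error computed directly (a noiseless curve fits exactly and
  # summary.lm would warn on the perfect fit)
  rss <- sum(stats::resid(fit)^2)
  se <- sqrt(rss / (nrow(curve) - 1) / sum(f_unit^2))
  structure(list(E = E,
                 residual_norm = sqrt(rss),
                 relative_se = unname(se / E),
                 n = nrow(curve),
                 nu = nu, R = R, fit = fit),
            class = "head_calibration")
}

#' @rdname calibrate_young_modulus
#' @param x,... print method arguments.
#' @export
print.head_calibration <- function(x, ...) {
  cat(sprintf(
    "<head_calibration> E = %.4f MPa (rel. SE %.2e, residual %.3g N, n = %d)\n",
    x$E, x$relative_se, x$residual_norm, x$n))
  invisible(x)
}
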