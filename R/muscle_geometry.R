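#' Per-muscle geometric specification
#'
#' Bundles the geometry that turns the shared centroid-radius curve into one
#' muscle's musculotendinous unit (MTU): the musculotendinous junction
#' position \code{beta} where belly becomes tendon, the insertion distance
#' \code{gamma} distal to the joint center, the stacking factor \code{phi}
#' that places the muscle's line of pull relative to the shared centroid
#' (the biceps lies superficial to the brachialis, so 3/2 vs 1/2), the
#' baseline pennation angle, and the proximal end of the belly.
#'
#' @param name muscle label.
#' @param beta MT-junction position, cm proximal to the joint center.
#' @param gamma insertion distance, cm distal to the joint center.
#' @param phi dimensionless stacking factor (> 0).
#' @param theta_p0 baseline pennation angle in degrees, in [0, 90).
#' @param belly_end proximal end of the muscle belly, cm.
#' @return object of class \code{"muscle_spec"}.
#' @seealso \code{\link{muscle_preset}} for the built-in BIC/BRA parameters.
#' @export
muscle_spec <- function(name, beta, gamma, phi, theta_p0, belly_end = 11.2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(beta), is.numeric(gamma), is.numeric(phi),
            is.numeric(theta_p0), is.numeric(belly_end))
  if (!(beta > 0 && beta < belly_end))
    stop("'beta' must satisfy 0 < beta < belly_end")
  if (gamma <= 0) stop("'gamma' must be positive")
  if (phi <= 0) stop("'phi' must be positive")
  if (theta_p0 < 0 || theta_p0 >= 90)
    stop("'theta_p0' must be in [0, 90) degrees")
  structure(list(name = name, beta = beta, gamma = gamma, phi = phi,
                 theta_p0 = theta_p0, belly_end = belly_end),
            class = "muscle_spec")
}

#' Built-in muscle presets
#'
#' The two modelled elbow flexors. Biceps brachii (\code{"BIC"}): MT junction
#' 1.1 cm proximal, insertion 4.51 cm distal (bicipital tuberosity), stacking
#' factor 3/2, baseline pennation 15 degrees. Brachialis (\code{"BRA"}): MT
#' junction 0.69 cm, insertion 3.17 cm (ulnar tuberosity/coronoid), stacking
#' factor 1/2, baseline pennation 10 degrees. Both bellies end 11.2 cm
#' proximal to the elbow. The pennation baselines are model-consistent
#' values recovered from the published baseline moment contributions and
#' validated against the atrophy/hypertrophy cells.
#'
#' @param name \code{"BIC"} or \code{"BRA"}.
#' @return a \code{\link{muscle_spec}}.
#' @export
muscle_preset <- function(name = c("BIC", "BRA")) {
  name <- match.arg(name)
  switch(name,
         BIC = muscle_spec("BIC", beta = 1.1, gamma = 4.51, phi = 3 / 2,
                           theta_p0 = 15),
         BRA = muscle_spec("BRA", beta = 0.69, gamma = 3.17, phi = 1 / 2,
                           theta_p0 = 10))
}

#' @export
print.muscle_spec <- function(x, ...) {
  cat(sprintf(
    "Muscle spec '%s': beta = %.3g cm, gamma = %.3g cm, phi = %.3g, theta_p0 = %.3g deg, belly end = %.3g cm\n",
    x$name, x$beta, x$gamma, x$phi, x$theta_p0, x$belly_end))
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("hypertrophy coefficient 'alpha' must be a positive finite number")
  if (alpha < 0.5 || alpha > 2.0)
    warning(sprintf(
      "alpha = %.3g is outside the modelled interval [0.5, 2.0]", alpha))
  invisible(alpha)
}

#' Tendon line of action
#'
#' The distal tendon is modelled as the tangent, at the musculotendinous
#' junction \code{beta}, to the muscle's scaled line-of-pull curve
#' \eqn{\varphi\sqrt{\alpha}\,r(x)}. Its slope is therefore
#' \eqn{\varphi\sqrt{\alpha}\,r'(\beta)}, so the line steepens as the belly
#' hypertrophies and the moment arm grows with it.
#'
#' Setting \code{literal_eq3 = TRUE} uses the unscaled slope
#' \eqn{r'(\beta)} instead. That variant leaves the insertion angle -- and
#' hence the moment arm -- independent of \code{alpha} and of the stacking
#' factor; it is retained only as a debugging comparison and does not
#' reproduce the published moment-arm table.
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param spec a \code{\link{muscle_spec}}.
#' @param alpha hypertrophy coefficient (ACSA scaling from baseline);
#'   values outside [0.5, 2] warn.
#' @param literal_eq3 use the unscaled tangent slope (debug only).
#' @return object of class \code{"tendon_line"}: list with \code{slope}
#'   (dimensionless) and \code{intercept} (height in cm at x = 0).
#' @export
tendon_line <- function(profile, spec, alpha = 1, literal_eq3 = FALSE) {
  stopifnot(inherits(spec, "muscle_spec"))
  check_alpha(alpha)
  scale <- spec$phi * sqrt(alpha)
  slope <- if (literal_eq3) radius_slope_at(profile, spec$beta)
           else scale * radius_slope_at(profile, spec$beta)
  height_at_beta <- scale * radius_at(profile, spec$beta)
  structure(list(slope = slope,
                 intercept = height_at_beta - slope * spec$beta,
                 muscle = spec$name, alpha = alpha),
            class = "tendon_line")
}

#' @export
print.tendon_line <- function(x, ...) {
  cat(sprintf("Tendon line (%s, alpha = %.3g): height = %.5g x + %.5g cm\n",
              x$muscle, x$alpha, x$slope, x$intercept))
  invisible(x)
}

#' Musculotendinous-unit height
#'
#' Piecewise curve of one muscle's line of pull above the humeral long axis:
#' the tendon tangent line distal to the MT junction (\code{x < beta}) and
#' the scaled centroid-radius curve \eqn{\varphi\sqrt{\alpha}\,r(x)} along
#' the belly (\code{beta <= x <= belly_end}). Continuous at \code{beta} by
#' the tangency construction.
#'
#' @inheritParams tendon_line
#' @param x position(s) in cm; must not exceed the belly end.
#' @return height(s) in cm.
#' @export
mtu_height <- function(profile, spec, alpha = 1, x, literal_eq3 = FALSE) {
  stopifnot(inherits(spec, "muscle_spec"), is.numeric(x))
  if (any(x > spec$belly_end))
    stop(sprintf("position x = %.4g cm is proximal to the belly end (%.4g cm)",
                 max(x), spec$belly_end))
  line <- tendon_line(profile, spec, alpha, literal_eq3)
  out <- numeric(length(x))
  belly <- x >= spec$beta
  out[!belly] <- line$slope * x[!belly] + line$intercept
  if (any(belly))
    out[belly] <- spec$phi * sqrt(alpha) * radius_at(profile, x[belly])
  out
}

#' Muscle moment arm about the elbow
#'
#' Perpendicular distance from the tendon line of action to the joint center
#' (origin). The insertion angle is \code{arctan} of the tendon slope
#' \eqn{s}, and the moment arm is the perpendicular component of the
#' insertion lever: \eqn{MA = \gamma \sin(\arctan s) = \gamma s/\sqrt{1+s^2}},
#' strictly below \eqn{\gamma} and strictly increasing in \code{alpha}
#' (through \eqn{s \propto \sqrt{\alpha}}).
#'
#' @inheritParams tendon_line
#' @return moment-arm length in cm.
#' @examples
#' moment_arm(acsa_profile(), muscle_preset("BIC"))      # ~2.17 cm at baseline
#' moment_arm(acsa_profile(), muscle_preset("BRA"), 2)   # ~1.03 cm doubled
#' @export
moment_arm <- function(profile, spec, alpha = 1, literal_eq3 = FALSE) {
  s <- tendon_line(profile, spec, alpha, literal_eq3)$slope
  spec$gamma * s / sqrt(1 + s^2)
}
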