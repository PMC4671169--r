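#' Mechanics configuration
#'
#' Holds the force-side constants: the normalized muscle force (specific
#' tension) and the per-muscle baseline ACSA. The default specific tension,
#' 30.75 N/cm^2, is the mean of commonly reported elbow-flexor values
#' (23, 30, 33, 37 N/cm^2) and is held constant across hypertrophy states.
#' The default per-muscle baseline ACSA, 11 cm^2, is half the combined
#' profile's 22 cm^2 peak under the equal-muscle-size assumption.
#'
#' @param nmf normalized muscle force, N/cm^2.
#' @param baseline_acsa per-muscle baseline maximum ACSA, cm^2.
#' @return object of class \code{"mechanics_config"}.
#' @export
mechanics_config <- function(nmf = 30.75, baseline_acsa = 11) {
  stopifnot(is.numeric(nmf), length(nmf) == 1L, nmf > 0,
            is.numeric(baseline_acsa), length(baseline_acsa) == 1L,
            baseline_acsa > 0)
  structure(list(nmf = nmf, baseline_acsa = baseline_acsa),
            class = "mechanics_config")
}

#' @export
print.mechanics_config <- function(x, ...) {
  cat(sprintf("Mechanics config: NMF = %.4g N/cm^2, baseline ACSA = %.4g cm^2 per muscle\n",
              x$nmf, x$baseline_acsa))
  invisible(x)
}

#' Pennation angle under hypertrophy
#'
#' Pennation is assumed to scale proportionally with maximum ACSA, so
#' \eqn{\theta_p(\alpha) = \alpha\,\theta_{p0}}. The result must stay below
#' 90 degrees, else no force component reaches the tendon.
#'
#' @param spec a \code{\link{muscle_spec}} (supplies \code{theta_p0}).
#' @param alpha hypertrophy coefficient.
#' @return pennation angle in degrees.
#' @export
pennation_angle <- function(spec, alpha = 1) {
  stopifnot(inherits(spec, "muscle_spec"))
  check_alpha(alpha)
  theta <- spec$theta_p0 * alpha
  if (theta >= 90)
    stop(sprintf("pennation angle %.3g deg >= 90 deg is nonphysical", theta))
  theta
}

#' Muscle force from cross-sectional area
#'
#' \eqn{F_{muscle} = ACSA \cdot NMF}. ACSA stands in for physiological CSA,
#' which is statistically indistinguishable from ACSA in the elbow flexors.
#'
#' @param acsa cross-sectional area, cm^2 (nonnegative).
#' @param config a \code{\link{mechanics_config}}.
#' @return force in N.
#' @export
muscle_force <- function(acsa, config = mechanics_config()) {
  stopifnot(inherits(config, "mechanics_config"), is.numeric(acsa))
  if (any(acsa < 0)) stop("'acsa' must be nonnegative")
  acsa * config$nmf
}

#' Tendon force: parallel component of muscle force
#'
#' \eqn{F_{tendon} = F_{muscle} \cos\theta_p}; only the component of
#' fascicle force along the longitudinal axis loads the tendon.
#'
#' @param f_muscle muscle force, N.
#' @param theta_p pennation angle in degrees, in [0, 90).
#' @return force in N, at most \code{f_muscle}.
#' @export
tendon_force <- function(f_muscle, theta_p) {
  stopifnot(is.numeric(f_muscle), is.numeric(theta_p))
  if (any(theta_p < 0) || any(theta_p >= 90))
    stop("'theta_p' must be in [0, 90) degrees")
  f_muscle * cos(theta_p * pi / 180)
}

#' Joint-moment contribution of one muscle
#'
#' \eqn{M = F_{tendon} \cdot MA}, with the moment arm supplied in cm and
#' converted to meters here, so the result is in N m.
#'
#' @param f_tendon tendon force, N (nonnegative).
#' @param ma moment arm, cm (nonnegative).
#' @return moment in N m.
#' @export
moment_contribution <- function(f_tendon, ma) {
  stopifnot(is.numeric(f_tendon), is.numeric(ma))
  if (any(f_tendon < 0) || any(ma < 0))
    stop("'f_tendon' and 'ma' must be nonnegative")
  f_tendon * (ma / 100)
}

#' Evaluate the full mechanics chain for one muscle and one alpha
#'
#' Composes geometry and mechanics: per-muscle ACSA is
#' \code{alpha * baseline_acsa} (uniform belly scaling of the maximum
#' cross section), the moment arm comes from the tendon tangent line at the
#' scaled MT junction, pennation scales proportionally with ACSA, and the
#' moment contribution is reported both with the alpha-dependent moment arm
#' (\code{moment_incl_ma}) and with the moment arm frozen at its baseline
#' alpha = 1 value (\code{moment_excl_ma}), isolating the moment-arm effect.
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param spec a \code{\link{muscle_spec}}.
#' @param alpha hypertrophy coefficient.
#' @param config a \code{\link{mechanics_config}}.
#' @param literal_eq3 use the unscaled tendon slope (debug only).
#' @return one-row data frame with columns \code{muscle}, \code{alpha},
#'   \code{acsa_cm2}, \code{ma_cm}, \code{theta_p_deg}, \code{f_muscle_n},
#'   \code{f_tendon_n}, \code{moment_incl_nm}, \code{moment_excl_nm}.
#' @examples
#' evaluate_muscle(acsa_profile(), muscle_preset("BIC"), alpha = 2)
#' @export
evaluate_muscle <- function(profile, spec, alpha = 1,
                            config = mechanics_config(),
                            literal_eq3 = FALSE) {
  acsa <- alpha * config$baseline_acsa
  ma <- moment_arm(profile, spec, alpha, literal_eq3)
  ma_base <- moment_arm(profile, spec, 1, literal_eq3)
  theta <- pennation_angle(spec, alpha)
  fm <- muscle_force(acsa, config)
  ft <- tendon_force(fm, theta)
  data.frame(muscle = spec$name, alpha = alpha, acsa_cm2 = acsa,
             ma_cm = ma, theta_p_deg = theta, f_muscle_n = fm,
             f_tendon_n = ft,
             moment_incl_nm = moment_contribution(ft, ma),
             moment_excl_nm = moment_contribution(ft, ma_base))
}
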