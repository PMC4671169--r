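#' Hyperbolic-cosine ACSA profile of the proximal elbow flexors
#'
#' Constructs the anatomical cross-sectional area (ACSA) versus position
#' profile of the combined biceps brachii + brachialis,
#' \deqn{ACSA(x) = d - \cosh(b (x - c)),}
#' where \code{x} is distance proximal to the elbow joint center in cm.
#' The default coefficients are the published regression against MRI-derived
#' elbow-flexor cross sections taken 2.4--11.2 cm proximal to the elbow.
#'
#' The profile is positive only on the open interval
#' \eqn{(c - \mathrm{arccosh}(d)/b,\; c + \mathrm{arccosh}(d)/b)}; evaluation
#' outside that support is an error rather than a clamped zero, because a
#' non-positive cross section is nonphysical.
#'
#' @param d_offset peak-area offset \eqn{d} in cm^2; must exceed 1.
#' @param b_width inverse-length shape coefficient \eqn{b} in 1/cm; positive.
#' @param c_peak position of the profile maximum in cm proximal to the elbow.
#' @return An object of class \code{"acsa_profile"}: a list with the three
#'   coefficients and the positive-support interval \code{support}.
#' @examples
#' p <- acsa_profile()
#' acsa_at(p, 7.3)   # 22 cm^2 at the peak
#' radius_at(p, 7.3) # centroid radius, sqrt(22/pi)
#' @export
acsa_profile <- function(d_offset = 23, b_width = 0.48, c_peak = 7.3) {
  stopifnot(is.numeric(d_offset), length(d_offset) == 1L, is.finite(d_offset),
            is.numeric(b_width), length(b_width) == 1L, is.finite(b_width),
            is.numeric(c_peak), length(c_peak) == 1L, is.finite(c_peak))
  if (d_offset <= 1)
    stop("'d_offset' must exceed 1 (the profile is nowhere positive otherwise)")
  if (b_width <= 0)
    stop("'b_width' must be positive")
  half <- acosh(d_offset) / b_width
  structure(
    list(d_offset = d_offset, b_width = b_width, c_peak = c_peak,
         support = c(c_peak - half, c_peak + half)),
    class = "acsa_profile")
}

#' @export
print.acsa_profile <- function(x, ...) {
  cat("ACSA profile: ACSA(x) = ", format(x$d_offset),
      " - cosh(", format(x$b_width), " (x - ", format(x$c_peak), "))\n",
      sep = "")
  cat(sprintf("  peak %.4g cm^2 at x = %.4g cm; positive support (%.4g, %.4g) cm\n",
              x$d_offset - 1, x$c_peak, x$support[1], x$support[2]))
  invisible(x)
}

check_support <- function(profile, x) {
  if (!inherits(profile, "acsa_profile"))
    stop("'profile' must be an 'acsa_profile' object")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  bad <- x <= profile$support[1] | x >= profile$support[2]
  if (any(bad))
    stop(sprintf(
      "position x = %.4g cm is outside the profile's positive support (%.4g, %.4g)",
      x[which(bad)[1]], profile$support[1], profile$support[2]))
  invisible(TRUE)
}

#' Evaluate the ACSA profile
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param x position(s) in cm proximal to the elbow joint center; must lie
#'   inside the profile's positive support.
#' @return ACSA in cm^2 (vectorized over \code{x}); strictly positive.
#' @export
acsa_at <- function(profile, x) {
  check_support(profile, x)
  profile$d_offset - cosh(profile$b_width * (x - profile$c_peak))
}

#' Centroid radius of the flexor cross section
#'
#' The combined flexor mass is treated as a cylinder, so the centroid height
#' of the cross section at \code{x} is the radius of a circle with the same
#' area: \eqn{r(x) = \sqrt{ACSA(x)/\pi}}.
#'
#' @inheritParams acsa_at
#' @return radius in cm.
#' @export
radius_at <- function(profile, x) {
  sqrt(acsa_at(profile, x) / pi)
}

#' Slope of the centroid-radius curve
#'
#' Closed-form derivative \eqn{r'(x) = ACSA'(x) / (2\pi r(x))} with
#' \eqn{ACSA'(x) = -b\,\sinh(b(x - c))}. This is the slope that defines the
#' tendon tangent line at the musculotendinous junction.
#'
#' @inheritParams acsa_at
#' @return dimensionless slope (cm per cm).
#' @export
radius_slope_at <- function(profile, x) {
  r <- radius_at(profile, x)
  dacsa <- -profile$b_width * sinh(profile$b_width * (x - profile$c_peak))
  dacsa / (2 * pi * r)
}

#' @describeIn acsa_profile evaluate area, radius or radius slope at new positions.
#' @param object an \code{"acsa_profile"}.
#' @param x positions in cm.
#' @param what which quantity to return.
#' @param ... ignored.
#' @export
predict.acsa_profile <- function(object, x,
                                 what = c("acsa", "radius", "slope"), ...) {
  what <- match.arg(what)
  switch(what,
         acsa   = acsa_at(object, x),
         radius = radius_at(object, x),
         slope  = radius_slope_at(object, x))
}
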