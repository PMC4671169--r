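#' Generate synthetic MRI-style ACSA measurements
#'
#' Draws position/area samples from an ACSA profile with additive Gaussian
#' measurement noise, emulating per-subject cross sections measured on MRI
#' slices between roughly 2.4 and 11.2 cm proximal to the elbow. Negative
#' noisy draws are clamped to 0 (areas are nonnegative). With
#' \code{noise_sd = 0} the exact profile values are returned.
#'
#' The global RNG state is left untouched: when \code{seed} is supplied the
#' generator is seeded locally and the previous \code{.Random.seed} restored
#' on exit, so repeated calls with the same seed are reproducible without
#' side effects.
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param xs positions in cm, inside the profile's positive support.
#' @param noise_sd standard deviation of the additive Gaussian noise, cm^2.
#' @param seed optional integer seed for reproducible draws.
#' @return data frame with columns \code{x} (cm) and \code{acsa} (cm^2).
#' @examples
#' simulate_acsa_samples(acsa_profile(), xs = c(2.4, 7.3, 11.2), noise_sd = 0)
#' @export
simulate_acsa_samples <- function(profile, xs, noise_sd = 0.5, seed = NULL) {
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  truth <- acsa_at(profile, xs)
  if (noise_sd == 0)
    return(data.frame(x = xs, acsa = truth))
  noise <- with_local_seed(seed, stats::rnorm(length(xs), sd = noise_sd))
  data.frame(x = xs, acsa = pmax(truth + noise, 0))
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
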