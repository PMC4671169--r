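#' Fit a hyperbolic-cosine ACSA profile to position/area measurements
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt via
#' \code{minpack.lm::nlsLM}) of the model
#' \eqn{ACSA(x) = d - \cosh(b(x - c))} to a table of positions (cm) and
#' cross-sectional areas (cm^2), minimising squared ACSA residuals.
#'
#' Starting values are data-driven: \code{c_peak} at the position of the
#' largest sampled area, \code{d_offset} at that maximum plus 1, and
#' \code{b_width = 0.5}; bounds are \code{b_width} in (0, 10] and
#' \code{d_offset} in (1, 1000]. At least 4 samples with at least 2 distinct
#' positions on each side of the sample maximum are required, otherwise the
#' three-parameter cosh is under-determined.
#'
#' @param samples a data frame with numeric columns \code{x} (cm) and
#'   \code{acsa} (cm^2), as produced by \code{\link{simulate_acsa_samples}}
#'   or read from a measurement CSV.
#' @return An object of class \code{"acsa_fit"}: list with elements
#'   \code{profile} (the fitted \code{\link{acsa_profile}}),
#'   \code{rms_residual} (cm^2), \code{converged}, \code{n_samples},
#'   \code{samples}, and the underlying \code{nls} fit.
#' @examples
#' xs <- seq(2.4, 11.2, length.out = 20)
#' fit <- fit_acsa_profile(simulate_acsa_samples(acsa_profile(), xs, noise_sd = 0))
#' coef(fit)
#' @export
fit_acsa_profile <- function(samples) {
  samples <- validate_samples(samples)
  imax <- which.max(samples$acsa)
  x0 <- samples$x[imax]
  n_left <- length(unique(samples$x[samples$x < x0]))
  n_right <- length(unique(samples$x[samples$x > x0]))
  if (nrow(samples) < 4L || n_left < 2L || n_right < 2L)
    stop("need >= 4 samples with >= 2 distinct positions on each side of the ",
         "sample maximum; got ", nrow(samples), " samples (",
         n_left, " left, ", n_right, " right)")

  start <- list(d_offset = max(samples$acsa) + 1, b_width = 0.5, c_peak = x0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      acsa ~ d_offset - cosh(b_width * (x - c_peak)),
      data = samples, start = start,
      lower = c(d_offset = 1 + 1e-9, b_width = 1e-9, c_peak = -Inf),
      upper = c(d_offset = 1e3, b_width = 10, c_peak = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    res <- list(profile = NULL, rms_residual = NA_real_, converged = FALSE,
                n_samples = nrow(samples), samples = samples, fit = NULL,
                message = conditionMessage(fit))
    class(res) <- "acsa_fit"
    return(res)
  }

  cf <- stats::coef(fit)
  profile <- acsa_profile(d_offset = cf[["d_offset"]],
                          b_width = cf[["b_width"]],
                          c_peak = cf[["c_peak"]])
  res <- list(profile = profile,
              rms_residual = sqrt(mean(stats::resid(fit)^2)),
              converged = fit$convInfo$isConv,
              n_samples = nrow(samples),
              samples = samples,
              fit = fit,
              message = fit$convInfo$stopMessage)
  class(res) <- "acsa_fit"
  res
}

validate_samples <- function(samples) {
  if (!is.data.frame(samples) || !all(c("x", "acsa") %in% names(samples)))
    stop("'samples' must be a data frame with columns 'x' and 'acsa'")
  if (!is.numeric(samples$x) || !is.numeric(samples$acsa) ||
      any(!is.finite(samples$x)) || any(!is.finite(samples$acsa)))
    stop("'x' and 'acsa' must be finite numeric")
  if (any(samples$acsa < 0))
    stop("negative ACSA values are nonphysical")
  samples[c("x", "acsa")]
}

#' @export
print.acsa_fit <- function(x, ...) {
  cat("Hyperbolic-cosine ACSA profile fit (", x$n_samples, " samples)\n",
      sep = "")
  if (!x$converged) {
    cat("  DID NOT CONVERGE: ", x$message, "\n", sep = "")
  } else {
    cf <- stats::coef(x)
    cat(sprintf("  d_offset = %.5g cm^2, b_width = %.5g 1/cm, c_peak = %.5g cm\n",
                cf[["d_offset"]], cf[["b_width"]], cf[["c_peak"]]))
    cat(sprintf("  RMS residual %.4g cm^2\n", x$rms_residual))
  }
  invisible(x)
}

#' @export
coef.acsa_fit <- function(object, ...) {
  if (is.null(object$profile)) return(c(d_offset = NA_real_,
                                        b_width = NA_real_,
                                        c_peak = NA_real_))
  with(object$profile,
       c(d_offset = d_offset, b_width = b_width, c_peak = c_peak))
}

#' @export
predict.acsa_fit <- function(object, x = object$samples$x, ...) {
  if (is.null(object$profile)) stop("fit did not converge; no profile to predict from")
  acsa_at(object$profile, x)
}

#' @export
residuals.acsa_fit <- function(object, ...) {
  object$samples$acsa - predict(object)
}

#' @export
summary.acsa_fit <- function(object, ...) {
  structure(list(fit = object,
                 nls_summary = if (!is.null(object$fit)) summary(object$fit)),
            class = "summary.acsa_fit")
}

#' @export
print.summary.acsa_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$nls_summary)) {
    cat("\nParameter table:\n")
    stats::printCoefmat(x$nls_summary$coefficients)
  }
  invisible(x)
}

#' @export
plot.acsa_fit <- function(x, ...) {
  plot(x$samples$x, x$samples$acsa, xlab = "x (cm proximal to elbow)",
       ylab = expression(ACSA ~ (cm^2)), ...)
  if (!is.null(x$profile)) {
    xx <- seq(min(x$samples$x), max(x$samples$x), length.out = 200)
    graphics::lines(xx, acsa_at(x$profile, xx))
  }
  invisible(x)
}
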