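#' Default hypertrophy grid
#'
#' Alpha values 0.5 to 2.0 in steps of 0.1, built by integer indexing
#' (\code{(5:20)/10}) so repeated floating-point addition cannot drift the
#' grid off the exact tenths.
#'
#' @return numeric vector of 16 alpha values.
#' @export
default_alpha_grid <- function() (5:20) / 10

# round half away from zero at `digits` decimals (the convention that
# reproduces every verified published table cell)
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Run the hypertrophy/atrophy sweep
#'
#' Evaluates the full mechanics chain (\code{\link{evaluate_muscle}}) for
#' every muscle and every alpha on the grid, producing the data behind the
#' published summary table and curve families (moment arm, pennation,
#' muscle/tendon force, and moment contributions with and without the
#' moment-arm change).
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param specs list of \code{\link{muscle_spec}} objects; defaults to the
#'   BIC and BRA presets.
#' @param config a \code{\link{mechanics_config}}.
#' @param grid strictly increasing vector of positive alpha values.
#' @param literal_eq3 use the unscaled tendon slope (debug only).
#' @return object of class \code{"flexor_sweep"}: a data frame with one row
#'   per (muscle, alpha), columns as in \code{\link{evaluate_muscle}}, plus
#'   attributes \code{grid}, \code{profile}, \code{specs}, \code{config}.
#' @examples
#' sw <- flexor_sweep()
#' summary(sw)
#' @export
flexor_sweep <- function(profile = acsa_profile(),
                         specs = list(muscle_preset("BIC"),
                                      muscle_preset("BRA")),
                         config = mechanics_config(),
                         grid = default_alpha_grid(),
                         literal_eq3 = FALSE) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (any(grid <= 0)) stop("all grid alpha values must be positive")
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing")
  if (inherits(specs, "muscle_spec")) specs <- list(specs)

  rows <- vector("list", length(specs) * length(grid))
  k <- 0L
  for (spec in specs) {
    for (a in grid) {
      k <- k + 1L
      rows[[k]] <- tryCatch(
        evaluate_muscle(profile, spec, a, config, literal_eq3),
        error = function(e) stop(sprintf(
          "sweep failed at muscle '%s', alpha = %.3g: %s",
          spec$name, a, conditionMessage(e)), call. = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, grid = grid, profile = profile, specs = specs,
            config = config,
            class = c("flexor_sweep", "data.frame"))
}

#' @export
print.flexor_sweep <- function(x, digits = 4, ...) {
  muscles <- unique(x$muscle)
  cat(sprintf("Elbow-flexor hypertrophy sweep: %d muscles x %d alpha values (alpha %.2g..%.2g)\n",
              length(muscles), length(attr(x, "grid")),
              min(attr(x, "grid")), max(attr(x, "grid"))))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Published-style summary of a sweep
#'
#' Extracts the atrophy (alpha = 0.5), baseline (alpha = 1) and hypertrophy
#' (alpha = 2) columns for ACSA, moment-arm length and both moment
#' contributions, rounded to two decimals (half away from zero), with delta
#' columns taken as differences of the rounded cells. Percent moment-arm
#' increase at doubled ACSA is reported both from the rounded cells (the
#' convention matching the published 27.2\%/37.3\%) and from full-precision
#' values.
#'
#' @param sweep a \code{\link{flexor_sweep}} whose grid contains 0.5, 1 and 2.
#' @return object of class \code{"table1_summary"}: list with the cell data
#'   frame \code{cells} and per-muscle moment-arm percent changes
#'   \code{ma_pct_change} (rounded convention) and
#'   \code{ma_pct_change_full} (full precision).
#' @export
summarize_table1 <- function(sweep) {
  stopifnot(inherits(sweep, "flexor_sweep"))
  need <- c(0.5, 1, 2)
  if (!all(need %in% sweep$alpha))
    stop("sweep grid must contain alpha = 0.5, 1.0 and 2.0")

  muscles <- unique(sweep$muscle)
  quantities <- c(acsa_cm2 = "ACSA (cm^2)",
                  ma_cm = "MA length (cm)",
                  moment_incl_nm = "moment contribution (N m) (incl. MA)",
                  moment_excl_nm = "moment contribution (N m) (excl. MA)")

  cell <- function(m, col, a)
    sweep[sweep$muscle == m & sweep$alpha == a, col]

  rows <- list()
  pct <- pct_full <- stats::setNames(numeric(length(muscles)), muscles)
  for (m in muscles) {
    for (col in names(quantities)) {
      v <- round_half_away(vapply(need, function(a) cell(m, col, a), 0))
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = m, quantity = quantities[[col]],
        atrophy = v[1], delta_ab = round_half_away(v[1] - v[2]),
        baseline = v[2], delta_hb = round_half_away(v[3] - v[2]),
        hypertrophy = v[3])
    }
    ma <- round_half_away(vapply(need, function(a) cell(m, "ma_cm", a), 0))
    pct[m] <- round_half_away((ma[3] - ma[2]) / ma[2] * 100, 1)
    pct_full[m] <- (cell(m, "ma_cm", 2) / cell(m, "ma_cm", 1) - 1) * 100
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  structure(list(cells = cells, ma_pct_change = pct,
                 ma_pct_change_full = pct_full),
            class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  cat("Atrophy (alpha = 0.5) / baseline (1.0) / hypertrophy (2.0) summary\n")
  print.data.frame(x$cells, row.names = FALSE)
  cat("\nMoment-arm increase for doubled ACSA (from rounded cells):\n")
  for (m in names(x$ma_pct_change))
    cat(sprintf("  %s: %.1f%% (full precision %.1f%%)\n", m,
                x$ma_pct_change[[m]], x$ma_pct_change_full[[m]]))
  invisible(x)
}

#' @describeIn flexor_sweep published-style three-column summary
#'   (see \code{\link{summarize_table1}}).
#' @param object a \code{"flexor_sweep"}.
#' @param ... ignored.
#' @export
summary.flexor_sweep <- function(object, ...) summarize_table1(object)

#' Moment-arm scaling characterization
#'
#' Quantifies how closely the relative moment-arm change tracks an
#' arcsine-of-square-root law in the ACSA ratio. Since
#' \eqn{MA(\alpha) = \gamma \sin(\arctan(s_1\sqrt{\alpha}))}, the candidate
#' predictor used here applies the arcsine to the square-root-scaled
#' baseline sine of the insertion angle:
#' \deqn{P(\alpha) = \arcsin(\sqrt{\alpha}\, MA(1)/\gamma) / \arcsin(MA(1)/\gamma).}
#' For each grid point the ratio of the observed relative change
#' \eqn{MA(\alpha)/MA(1)} to \eqn{P(\alpha)} is computed; the coefficient of
#' variation of that ratio over the grid is reported as a constancy score.
#' The law is approximate, so the score characterizes it without asserting
#' proportionality.
#'
#' @param sweep a \code{\link{flexor_sweep}} with at least 3 grid points
#'   including alpha = 1.
#' @return object of class \code{"ma_scaling_report"}: per-muscle data
#'   frames of alpha, observed ratio, predictor and their ratio, plus the
#'   constancy score (CV).
#' @export
ma_scaling_check <- function(sweep) {
  stopifnot(inherits(sweep, "flexor_sweep"))
  grid <- attr(sweep, "grid")
  if (length(grid) < 3L)
    stop("scaling characterization needs a grid of at least 3 alpha values")
  if (!1 %in% grid)
    stop("grid must contain the baseline alpha = 1")

  specs <- attr(sweep, "specs")
  names(specs) <- vapply(specs, `[[`, "", "name")
  out <- list()
  for (m in unique(sweep$muscle)) {
    sub <- sweep[sweep$muscle == m, ]
    ma1 <- sub$ma_cm[sub$alpha == 1]
    gamma <- specs[[m]]$gamma
    arg <- sqrt(sub$alpha) * ma1 / gamma
    if (any(arg >= 1))
      stop(sprintf(
        "arcsine predictor undefined for muscle '%s' at alpha = %.3g",
        m, sub$alpha[which(arg >= 1)[1]]))
    predictor <- asin(arg) / asin(ma1 / gamma)
    observed <- sub$ma_cm / ma1
    ratio <- observed / predictor
    out[[m]] <- list(
      table = data.frame(alpha = sub$alpha, observed_ratio = observed,
                         arcsin_predictor = predictor, ratio = ratio),
      constancy_cv = stats::sd(ratio) / mean(ratio))
  }
  structure(out, class = "ma_scaling_report")
}

#' @export
print.ma_scaling_report <- function(x, ...) {
  cat("Relative moment-arm change vs arcsine(sqrt(ACSA ratio)) predictor\n")
  for (m in names(x))
    cat(sprintf("  %s: ratio CV over grid = %.4g (1 would be exact proportionality everywhere)\n",
                m, x[[m]]$constancy_cv))
  invisible(x)
}

#' @describeIn flexor_sweep plot the sweep's curve families: moment arm,
#'   pennation angle, muscle and tendon force, and moment contributions with
#'   and without the moment-arm change, all against per-muscle ACSA.
#' @param x a \code{"flexor_sweep"}.
#' @export
plot.flexor_sweep <- function(x, ...) {
  muscles <- unique(x$muscle)
  cols <- stats::setNames(seq_along(muscles) + 1L, muscles)
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(col, ylab, main, dashed_col = NULL) {
    graphics::matplot(
      matrix(x$acsa_cm2, ncol = length(muscles)),
      matrix(x[[col]], ncol = length(muscles)),
      type = "l", lty = 1, col = cols, xlab = expression(ACSA ~ (cm^2)),
      ylab = ylab, main = main)
    if (!is.null(dashed_col))
      graphics::matlines(
        matrix(x$acsa_cm2, ncol = length(muscles)),
        matrix(x[[dashed_col]], ncol = length(muscles)),
        lty = 2, col = cols)
    graphics::abline(v = attr(x, "config")$baseline_acsa, col = "grey")
  }
  panel("ma_cm", "moment arm (cm)", "A: moment arm")
  panel("theta_p_deg", "pennation (deg)", "B: pennation angle")
  panel("f_muscle_n", "muscle force (N)", "C: muscle force")
  panel("f_tendon_n", "tendon force (N)", "D: tendon force")
  panel("moment_incl_nm", "moment (N m)", "E: moment incl./excl. MA",
        dashed_col = "moment_excl_nm")
  graphics::plot.new()
  graphics::legend("center", legend = muscles, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Write sweep and summary tables as CSV
#'
#' \code{write_sweep_csv} writes the full per-(muscle, alpha) sweep;
#' \code{write_table1_csv} writes the three-condition summary cells.
#' Both are plain deterministic CSV (no row names), so identical inputs
#' produce byte-identical files.
#'
#' @param sweep a \code{\link{flexor_sweep}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @param table1 a \code{\link{summarize_table1}} result (computed from
#'   \code{sweep} if missing).
#' @export
write_table1_csv <- function(sweep, path, table1 = summarize_table1(sweep)) {
  utils::write.csv(table1$cells, path, row.names = FALSE)
  invisible(path)
}
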