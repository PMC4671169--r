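#' Read a plain-text key-value model configuration
#'
#' Parses a small INI-style file with `[section]` headers and `key = value`
#' lines (`#` comments and blank lines ignored). Recognised sections are
#' `[profile]` (`d_offset`, `b_width`, `c_peak`), `[muscle.BIC]` /
#' `[muscle.BRA]` (`beta_cm`, `gamma_cm`, `phi`, `theta_p0_deg`,
#' `belly_end_cm`), `[mechanics]` (`nmf_n_per_cm2`, `baseline_acsa_cm2`) and
#' `[sweep]` (`alpha_grid`, comma-separated). Values are parsed as numeric
#' where possible.
#'
#' @param path path to the config file.
#' @return nested named list, one element per section.
#' @export
read_flexor_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("config parse error at line %d: expected 'key = value', got '%s'",
                   i, lines[i]))
    if (is.null(section))
      stop(sprintf("config parse error at line %d: key before any [section]", i))
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (grepl(",", val, fixed = TRUE)) {
      num <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
      if (!any(is.na(num))) val <- num
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    cfg[[section]][[key]] <- val
  }
  cfg
}

#' Write a fitted profile as a key-value config block
#'
#' Serialises an \code{\link{acsa_profile}} as a `[profile]` section that
#' \code{\link{read_flexor_config}} can read back.
#'
#' @param profile an \code{\link{acsa_profile}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile_config <- function(profile, path) {
  stopifnot(inherits(profile, "acsa_profile"))
  writeLines(c(
    "[profile]",
    sprintf("d_offset = %.17g", profile$d_offset),
    sprintf("b_width = %.17g", profile$b_width),
    sprintf("c_peak = %.17g", profile$c_peak)), path)
  invisible(path)
}

# Resolve one parameter with provenance: flag > file > builtin.
resolve_param <- function(name, builtin, file_val = NULL, flag_val = NULL) {
  if (!is.null(flag_val))
    list(value = flag_val, source = "flag")
  else if (!is.null(file_val))
    list(value = file_val, source = "file")
  else
    list(value = builtin, source = "builtin")
}

#' Resolve a full run configuration
#'
#' Merges built-in model constants, an optional config file and explicit
#' overrides into a concrete model, recording the source of every effective
#' parameter (builtin / file / flag) for provenance logging.
#'
#' @param file_cfg nested list from \code{\link{read_flexor_config}}, or NULL.
#' @param overrides named list of flag-level overrides; recognised names:
#'   \code{nmf}, \code{baseline_acsa}, \code{alpha_grid}, \code{d_offset},
#'   \code{b_width}, \code{c_peak}.
#' @return list with \code{profile}, \code{specs}, \code{config} (mechanics),
#'   \code{grid} and a \code{provenance} data frame.
#' @export
resolve_run_config <- function(file_cfg = NULL, overrides = list()) {
  prov <- list()
  take <- function(name, builtin, section, key, flag = NULL) {
    r <- resolve_param(name, builtin,
                       file_val = file_cfg[[section]][[key]],
                       flag_val = flag)
    prov[[name]] <<- data.frame(parameter = name, source = r$source,
                                value = paste(format(r$value), collapse = ","))
    r$value
  }

  profile <- acsa_profile(
    d_offset = take("profile.d_offset", 23, "profile", "d_offset",
                    overrides$d_offset),
    b_width = take("profile.b_width", 0.48, "profile", "b_width",
                   overrides$b_width),
    c_peak = take("profile.c_peak", 7.3, "profile", "c_peak",
                  overrides$c_peak))

  make_spec <- function(name) {
    base <- muscle_preset(name)
    sec <- paste0("muscle.", name)
    muscle_spec(
      name,
      beta = take(paste0(sec, ".beta_cm"), base$beta, sec, "beta_cm"),
      gamma = take(paste0(sec, ".gamma_cm"), base$gamma, sec, "gamma_cm"),
      phi = take(paste0(sec, ".phi"), base$phi, sec, "phi"),
      theta_p0 = take(paste0(sec, ".theta_p0_deg"), base$theta_p0, sec,
                      "theta_p0_deg"),
      belly_end = take(paste0(sec, ".belly_end_cm"), base$belly_end, sec,
                       "belly_end_cm"))
  }
  specs <- list(make_spec("BIC"), make_spec("BRA"))

  config <- mechanics_config(
    nmf = take("mechanics.nmf_n_per_cm2", 30.75, "mechanics",
               "nmf_n_per_cm2", overrides$nmf),
    baseline_acsa = take("mechanics.baseline_acsa_cm2", 11, "mechanics",
                         "baseline_acsa_cm2", overrides$baseline_acsa))

  grid <- take("sweep.alpha_grid", default_alpha_grid(), "sweep",
               "alpha_grid", overrides$alpha_grid)
  grid <- sort(unique(as.numeric(grid)))

  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  list(profile = profile, specs = specs, config = config, grid = grid,
       provenance = provenance)
}
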