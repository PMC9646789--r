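#' Study configuration
#'
#' Bundles the knobs shared across the pipeline: which fraction-affected
#' values are admissible for fitting, how wide the "additive" CI band is,
#' which part of a kinetic trace the velocity is read from, the logarithm
#' base of the median-effect plot, the seed for synthetic runs and the
#' number of decimals used in formatted report mirrors.
#'
#' @param clip_bounds Length-2 numeric, the open interval of fraction
#'   affected (fa) values admitted into median-effect fitting. Points
#'   outside are flagged, never dropped silently. Must satisfy
#'   `0 < low < 0.5 < high < 1`.
#' @param additive_band Half-width of the CI band labelled "additive":
#'   `|CI - 1| <= additive_band`. Non-negative.
#' @param velocity_window `"full"` (use every timepoint) or `"auto"`
#'   (best contiguous window by r-squared, see [fit_velocity()]).
#' @param log_base Base of the logarithm used for median-effect plot
#'   coordinates. Slope and correlation are base-invariant; 10 is the
#'   conventional choice.
#' @param seed Integer seed recorded into synthetic fixtures and reports.
#' @param output_precision Decimal places for the formatted mirror of
#'   numeric values in reports.
#'
#' @return A list of class `chousyn_config`.
#' @examples
#' cfg <- study_config(additive_band = 0.05)
#' cfg$clip_bounds
#' @export
study_config <- function(clip_bounds = c(0.005, 0.995),
                         additive_band = 0.05,
                         velocity_window = c("full", "auto"),
                         log_base = 10,
                         seed = 1L,
                         output_precision = 2L) {
  velocity_window <- match.arg(velocity_window)
  if (length(clip_bounds) != 2L || !is.numeric(clip_bounds)) {
    abort("`clip_bounds` must be a numeric vector of length 2.",
          class = "chousyn_config_error")
  }
  clip_bounds <- sort(as.numeric(clip_bounds))
  if (!(clip_bounds[1] > 0 && clip_bounds[1] < 0.5 &&
        clip_bounds[2] > 0.5 && clip_bounds[2] < 1)) {
    abort("`clip_bounds` must satisfy 0 < low < 0.5 < high < 1.",
          class = "chousyn_config_error")
  }
  if (!is.numeric(additive_band) || length(additive_band) != 1L ||
      is.na(additive_band) || additive_band < 0) {
    abort("`additive_band` must be a single non-negative number.",
          class = "chousyn_config_error")
  }
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1) {
    abort("`log_base` must be a single number > 1.",
          class = "chousyn_config_error")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    abort("`seed` must be a single integer.", class = "chousyn_config_error")
  }
  if (!is.numeric(output_precision) || length(output_precision) != 1L ||
      output_precision < 0) {
    abort("`output_precision` must be a single non-negative integer.",
          class = "chousyn_config_error")
  }
  structure(
    list(
      clip_bounds = c(low = clip_bounds[1], high = clip_bounds[2]),
      additive_band = as.numeric(additive_band),
      velocity_window = velocity_window,
      log_base = as.numeric(log_base),
      seed = as.integer(seed),
      output_precision = as.integer(output_precision)
    ),
    class = "chousyn_config"
  )
}

#' @export
print.chousyn_config <- function(x, ...) {
  cat("<chousyn study configuration>\n")
  cat(sprintf("  fa clip bounds : (%g, %g)\n",
              x$clip_bounds[["low"]], x$clip_bounds[["high"]]))
  cat(sprintf("  additive band  : |CI - 1| <= %g\n", x$additive_band))
  cat(sprintf("  velocity window: %s\n", x$velocity_window))
  cat(sprintf("  log base       : %g\n", x$log_base))
  cat(sprintf("  seed           : %d\n", x$seed))
  invisible(x)
}

#' Read a study configuration from a JSON file
#'
#' The file maps field names exactly onto [study_config()] arguments;
#' missing fields take the defaults.
#'
#' @param path Path to a JSON file.
#' @return A `chousyn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "chousyn_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("Unknown config field(s) in %s: %s", path,
                  paste(extra, collapse = ", ")),
          class = "chousyn_config_error")
  }
  do.call(study_config, raw)
}

as_config <- function(config) {
  if (is.null(config)) return(study_config())
  if (inherits(config, "chousyn_config")) return(config)
  if (is.list(config)) return(do.call(study_config, config))
  abort("`config` must be NULL, a chousyn_config, or a named list.",
        class = "chousyn_config_error")
}
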