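#' Read kinetic absorbance traces from CSV
#'
#' Reads one or more wells' absorbance-versus-time reads. The file must
#' carry the columns `time_min`, `a600`, `agent`, `dose`, `dose_unit`,
#' `replicate`, `is_control`; each (agent, dose, replicate) group is one
#' well. Validation is total: every malformed row raises an error naming
#' the file, the row and the rule violated — nothing is silently coerced.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal,
#'   header required).
#' @return A tibble with one row per timepoint, columns `time_min`
#'   (minutes), `a600` (absorbance units), `agent`, `dose`, `dose_unit`,
#'   `replicate` (integer), `is_control` (logical), sorted by well and
#'   time. Within each well times are strictly increasing.
#' @seealso [build_dose_effect()] which turns traces into dose-effect
#'   points, [simulate_single_agent_study()] which generates them.
#' @export
read_trace_csv <- function(path) {
  raw <- read_checked_csv(path, c("time_min", "a600", "agent", "dose",
                                  "dose_unit", "replicate", "is_control"))
  if (nrow(raw) == 0L) {
    warn(sprintf("No data rows in %s; returning an empty trace collection.",
                 path))
    return(tibble(time_min = double(), a600 = double(), agent = character(),
                  dose = double(), dose_unit = character(),
                  replicate = integer(), is_control = logical()))
  }
  out <- tibble(
    time_min = parse_num(raw, "time_min", path),
    a600 = parse_num(raw, "a600", path),
    agent = raw$agent,
    dose = parse_num(raw, "dose", path),
    dose_unit = raw$dose_unit,
    replicate = as.integer(parse_num(raw, "replicate", path)),
    is_control = parse_flag(raw, "is_control", path)
  )
  bad_ctrl <- which(out$is_control & out$dose != 0)
  if (length(bad_ctrl)) {
    abort(sprintf("%s row %d: control wells must have dose = 0 (got %g).",
                  path, bad_ctrl[1] + 1L, out$dose[bad_ctrl[1]]),
          class = "chousyn_validation_error")
  }
  check_unit_consistency(out, path)
  key <- paste(out$agent, out$dose, out$replicate, out$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort(sprintf(
      "%s row %d: duplicate record for (agent=%s, dose=%g, replicate=%d, time=%g).",
      path, d + 1L, out$agent[d], out$dose[d], out$replicate[d],
      out$time_min[d]), class = "chousyn_duplicate_error")
  }
  arrange(out, .data$agent, .data$dose, .data$replicate, .data$time_min)
}

#' Read a dose-effect table from CSV
#'
#' Reads (dose, fraction affected) points, the direct input to
#' [fit_median_effect()]. Required columns: `agent`, `dose`, `dose_unit`,
#' `fa`; an optional `n_replicates` column is carried through (default 1).
#' Doses must be positive and fa must lie in \[0, 1\]. Points whose fa
#' falls outside the configured clip bounds are flagged `fittable = FALSE`
#' but retained — the median-effect linearization is undefined at fa of 0
#' or 1 and ill-conditioned next to them.
#'
#' @param path Path to a CSV file.
#' @param config A [study_config()] (or named list of its arguments)
#'   supplying `clip_bounds`.
#' @return A tibble with columns `agent`, `dose`, `dose_unit`, `fa`,
#'   `n_replicates`, `fittable`.
#' @export
read_dose_effect_csv <- function(path, config = NULL) {
  config <- as_config(config)
  raw <- read_checked_csv(path, c("agent", "dose", "dose_unit", "fa"))
  if (nrow(raw) == 0L) {
    warn(sprintf("No data rows in %s; returning an empty dose-effect table.",
                 path))
    return(tibble(agent = character(), dose = double(),
                  dose_unit = character(), fa = double(),
                  n_replicates = integer(), fittable = logical()))
  }
  out <- tibble(
    agent = raw$agent,
    dose = parse_num(raw, "dose", path),
    dose_unit = raw$dose_unit,
    fa = parse_num(raw, "fa", path),
    n_replicates = if ("n_replicates" %in% names(raw)) {
      as.integer(parse_num(raw, "n_replicates", path))
    } else 1L
  )
  if (any(out$dose <= 0)) {
    i <- which(out$dose <= 0)[1]
    abort(sprintf("%s row %d: dose must be > 0 (got %g); log(D) is undefined.",
                  path, i + 1L, out$dose[i]),
          class = "chousyn_validation_error")
  }
  if (any(out$fa < 0 | out$fa > 1)) {
    i <- which(out$fa < 0 | out$fa > 1)[1]
    abort(sprintf("%s row %d: fa must lie in [0, 1] (got %g).",
                  path, i + 1L, out$fa[i]),
          class = "chousyn_validation_error")
  }
  check_unit_consistency(out, path)
  out <- flag_fittable(out, config)
  n_flagged <- sum(!out$fittable)
  if (n_flagged > 0) {
    inform(sprintf(
      "%d of %d points in %s fall outside fa clip bounds (%g, %g) and are flagged non-fittable.",
      n_flagged, nrow(out), path,
      config$clip_bounds[["low"]], config$clip_bounds[["high"]]))
  }
  out
}

#' Read per-compound docking scores and per-plant totals
#'
#' @param scores_path CSV with columns `plant`, `compound_id`, `xp_gscore`
#'   (kcal/mol, more negative = better predicted binding).
#' @param totals_path CSV with columns `plant`, `total_in_database` (how
#'   many constituents of that plant the screened database holds).
#' @return A list with tibbles `scores` and `totals`; every plant in
#'   `scores` must appear in `totals` and totals must be at least the
#'   number of scored compounds.
#' @export
read_docking_csv <- function(scores_path, totals_path) {
  scores_raw <- read_checked_csv(scores_path,
                                 c("plant", "compound_id", "xp_gscore"))
  totals_raw <- read_checked_csv(totals_path, c("plant", "total_in_database"))
  scores <- tibble(
    plant = scores_raw$plant,
    compound_id = scores_raw$compound_id,
    xp_gscore = parse_num(scores_raw, "xp_gscore", scores_path)
  )
  totals <- tibble(
    plant = totals_raw$plant,
    total_in_database = as.integer(parse_num(totals_raw, "total_in_database",
                                             totals_path))
  )
  if (anyDuplicated(totals$plant)) {
    abort(sprintf("%s: duplicated plant in totals table.", totals_path),
          class = "chousyn_duplicate_error")
  }
  missing <- setdiff(unique(scores$plant), totals$plant)
  if (length(missing)) {
    abort(sprintf("%s: no total_in_database for plant(s): %s",
                  totals_path, paste(missing, collapse = ", ")),
          class = "chousyn_validation_error")
  }
  counts <- dplyr::count(scores, .data$plant, name = "n_scored")
  chk <- left_join(counts, totals, by = "plant")
  bad <- chk$total_in_database < chk$n_scored
  if (any(bad)) {
    abort(sprintf(
      "%s: plant %s has %d scored compounds but total_in_database = %d.",
      totals_path, chk$plant[bad][1], chk$n_scored[bad][1],
      chk$total_in_database[bad][1]),
      class = "chousyn_validation_error")
  }
  list(scores = scores, totals = totals)
}

#' Write an analysis report to JSON
#'
#' Serializes fitted single-agent curves and combination assessments into
#' a single JSON document: a `fits` section mirroring the (Dm, m, r)
#' parameter-table layout, a `combinations` section with per-effect-level
#' CI/DRI tables and isobologram coordinates, and a `provenance` block
#' (config snapshot, seed, input file MD5 digests, package version).
#' Numeric values are stored at full precision alongside a formatted
#' mirror at `config$output_precision` decimals. Re-running with the same
#' inputs and config yields a byte-identical numeric payload.
#'
#' @param results A list with elements `fits` (list of `medfit` objects,
#'   at least one) and optionally `combinations` (list of
#'   `combo_assessment` objects, see [assess_combination()]) and `hill`
#'   (list of `hillfit` objects).
#' @param path Output file path.
#' @param config A [study_config()]; governs the formatted mirror.
#' @param inputs Character vector of input file paths to digest into the
#'   provenance block (optional).
#' @return Invisibly, the report list that was written.
#' @export
write_report <- function(results, path, config = NULL, inputs = character()) {
  config <- as_config(config)
  fits <- results$fits
  if (is.null(fits) || length(fits) == 0L) {
    abort("`results$fits` must contain at least one fitted curve.",
          class = "chousyn_validation_error")
  }
  if (inherits(fits, "medfit")) fits <- list(fits)
  fmt <- function(x) formatC(x, digits = config$output_precision,
                             format = "f")
  fit_block <- function(f) {
    list(agent = f$agent, dose_unit = f$dose_unit,
         Dm = f$Dm, m = f$m, r = f$r, n_points = f$n_points,
         formatted = list(Dm = fmt(f$Dm), m = fmt(f$m), r = fmt(f$r)))
  }
  hill_block <- function(h) {
    list(agent = h$agent, ic50 = h$ic50, hill_slope = h$hill_slope,
         bottom = h$bottom, top = h$top, converged = h$converged,
         rss = h$rss,
         formatted = list(ic50 = fmt(h$ic50), hill_slope = fmt(h$hill_slope)))
  }
  combo_block <- function(cb) {
    pts <- cb$points
    list(
      agent_a = cb$agent_a, agent_b = cb$agent_b,
      ratio_fractions = cb$ratio_fractions,
      mixture_fit = fit_block(cb$fit_combo),
      points = lapply(seq_len(nrow(pts)), function(i) {
        p <- as.list(pts[i, ])
        p$formatted <- list(ci = fmt(p$ci), dri_a = fmt(p$dri_a),
                            dri_b = fmt(p$dri_b))
        p
      }),
      isobologram = lapply(seq_len(nrow(cb$isobologram)), function(i) {
        as.list(cb$isobologram[i, ])
      })
    )
  }
  digests <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(setNames(unname(tools::md5sum(existing)), basename(existing)))
  } else NULL
  report <- list(
    fits = lapply(fits, fit_block),
    hill = if (length(results$hill)) lapply(results$hill, hill_block),
    combinations = if (length(results$combinations)) {
      lapply(results$combinations, combo_block)
    } else list(),
    provenance = list(
      config = unclass(config),
      seed = config$seed,
      input_digests = digests,
      package = as.character(utils::packageVersion("chousyn"))
    )
  )
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) abort(
                    sprintf("Cannot open %s for writing: %s", path,
                            conditionMessage(e)),
                    class = "chousyn_io_error"))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), con)
  invisible(report)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return The report as a list; full-precision numeric fields round-trip
#'   exactly.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Report not found: %s", path), class = "chousyn_io_error")
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Export a CI/DRI table as flat CSV
#'
#' Machine twin of a per-effect-level combination table: one row per
#' effect level with component doses, equipotent single-agent doses,
#' CI, both DRIs and the interaction label.
#'
#' @param points A tibble of combination points (from [fa_ci_profile()] or
#'   `assess_combination()$points`).
#' @param path Output CSV path.
#' @return Invisibly, the tibble written.
#' @export
write_ci_table_csv <- function(points, path) {
  cols <- c("fa", "dose_a", "dose_b", "dx_a", "dx_b", "ci",
            "dri_a", "dri_b", "label")
  missing <- setdiff(cols, names(points))
  if (length(missing)) {
    abort(sprintf("CI table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "chousyn_schema_error")
  }
  readr::write_csv(points[cols], path)
  invisible(points[cols])
}

# -- internal CSV plumbing ---------------------------------------------------

# Read everything as character so that per-cell validation can report the
# 1-based data row (header excluded) of the first offending value.
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "chousyn_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "chousyn_schema_error")
  }
  raw
}

parse_num <- function(raw, col, path) {
  x <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(x) & !is.na(raw[[col]]))
  if (is.null(raw[[col]])) bad <- integer()
  nas <- which(is.na(raw[[col]]))
  bad <- sort(c(bad, nas))
  if (length(bad)) {
    abort(sprintf("%s row %d: column '%s' is not numeric (got '%s').",
                  path, bad[1] + 1L, col,
                  raw[[col]][bad[1]] %||% "NA"),
          class = "chousyn_parse_error")
  }
  x
}

parse_flag <- function(raw, col, path) {
  x <- tolower(trimws(raw[[col]]))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    abort(sprintf("%s row %d: column '%s' is not a logical flag (got '%s').",
                  path, i + 1L, col, raw[[col]][i]),
          class = "chousyn_parse_error")
  }
  out
}

check_unit_consistency <- function(df, path) {
  # control wells (dose 0) carry no meaningful unit
  dosed <- if ("is_control" %in% names(df)) df[df$dose != 0, ] else df
  units <- distinct(dosed, .data$agent, .data$dose_unit)
  dup <- units$agent[duplicated(units$agent)]
  if (length(dup)) {
    mixed <- units$dose_unit[units$agent == dup[1]]
    abort(sprintf("%s: agent '%s' uses mixed dose units (%s); one unit per agent.",
                  path, dup[1], paste(mixed, collapse = ", ")),
          class = "chousyn_unit_error")
  }
  invisible(df)
}

flag_fittable <- function(points, config) {
  lo <- config$clip_bounds[["low"]]
  hi <- config$clip_bounds[["high"]]
  mutate(points,
         fittable = .data$dose > 0 & .data$fa >= lo & .data$fa <= hi)
}
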