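# Orchestration layer: one function per analysis stage, each consuming
# files or tibbles/fit objects, attaching the failing stage's name to
# propagated errors and embedding a run manifest into every report.

with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    error = function(e) {
      if (inherits(e, "chousyn_staged_error")) stop(e)
      abort(sprintf("[%s] %s", stage, conditionMessage(e)),
            class = c("chousyn_staged_error", class(e)[1]))
    })
}

#' Run manifest
#'
#' Provenance block embedded in every pipeline report: the command, a
#' config snapshot, MD5 digests of the input files, the package version,
#' the seed and a timestamp.
#'
#' @param command Stage name.
#' @param config A [study_config()].
#' @param inputs Character vector of input paths (digested if they
#'   exist).
#' @return A list.
#' @export
run_manifest <- function(command, config, inputs = character()) {
  existing <- inputs[file.exists(inputs)]
  list(
    command = command,
    config = unclass(config),
    seed = config$seed,
    input_digests = if (length(existing)) {
      as.list(setNames(unname(tools::md5sum(existing)), basename(existing)))
    },
    package_version = as.character(utils::packageVersion("chousyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

detect_csv_kind <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (all(c("time_min", "a600") %in% hdr)) "trace"
  else if (all(c("dose", "fa") %in% hdr)) "dose_effect"
  else abort(sprintf("%s: header matches neither the trace nor the dose-effect schema.",
                     path), class = "chousyn_schema_error")
}

#' Fit stage: dose-effect parameters per agent
#'
#' Reads either a kinetic-trace CSV (converted through the velocity /
#' percent-inhibition chain) or a dose-effect CSV, then fits the
#' median-effect model per agent, optionally adding the constrained Hill
#' IC50 fit. The two input routes give identical parameters on noiseless
#' data.
#'
#' @param input Path to a CSV (kind auto-detected from the header) or a
#'   dose-effect tibble.
#' @param config A [study_config()].
#' @param hill Also fit the constrained 4PL per agent (needs >= 3
#'   fittable points)?
#' @param out Optional path: write the JSON report there.
#' @return A list: `fits` (named list of `medfit`), `hill` (named list of
#'   `hillfit` or NULL), `dose_effect` (the point table), `summary`
#'   (glance tibble, one row per agent), `manifest`.
#' @export
run_fit <- function(input, config = NULL, hill = FALSE, out = NULL) {
  config <- as_config(config)
  inputs <- character()
  if (is.character(input)) {
    inputs <- input
    kind <- detect_csv_kind(input)
    points <- if (kind == "trace") {
      traces <- with_stage("dataio", read_trace_csv(input))
      with_stage("kinetics", build_dose_effect(traces, config))
    } else {
      with_stage("dataio", read_dose_effect_csv(input, config))
    }
  } else {
    points <- flag_fittable(as_tibble(input), config)
  }
  inform(sprintf("fit: %d dose-effect points (%d fittable) across %d agent(s).",
                 nrow(points), sum(points$fittable),
                 length(unique(points$agent))))
  agents <- unique(points$agent)
  fits <- lapply(agents, function(a) {
    with_stage("median_effect",
               fit_median_effect(filter(points, .data$agent == a), config))
  })
  names(fits) <- agents
  hill_fits <- NULL
  if (hill) {
    hill_fits <- lapply(agents, function(a) {
      with_stage("median_effect",
                 fit_hill(filter(points, .data$agent == a), config = config))
    })
    names(hill_fits) <- agents
  }
  res <- list(fits = fits, hill = hill_fits, dose_effect = points,
              summary = purrr::map(fits, glance) |> list_rbind(),
              manifest = run_manifest("fit", config, inputs))
  if (!is.null(out)) {
    write_report(res, out, config = config, inputs = inputs)
  }
  res
}

#' Combine stage: CI/DRI analysis of a fixed-ratio combination
#'
#' @param fit_a,fit_b Single-agent `medfit` objects (e.g. from
#'   [run_fit()] or [medfit()]).
#' @param fit_combo The mixture's `medfit` on the total-dose axis.
#' @param ratio_fractions Length-2 fractions summing to 1; default
#'   Dm-proportional.
#' @param levels Effect levels (non-empty, each in (0, 1)).
#' @param config A [study_config()].
#' @param out Optional JSON report path.
#' @param out_csv Optional flat CSV path for the CI/DRI table.
#' @return The `combo_assessment`, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
run_combine <- function(fit_a, fit_b, fit_combo, ratio_fractions = NULL,
                        levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        config = NULL, out = NULL, out_csv = NULL) {
  config <- as_config(config)
  if (length(levels) == 0L) {
    abort("`levels` must be non-empty.", class = "chousyn_domain_error")
  }
  if (fit_a$dose_unit != "" && fit_b$dose_unit != "" &&
      identical(fit_a$agent, fit_b$agent) &&
      !identical(fit_a$dose_unit, fit_b$dose_unit)) {
    abort(sprintf("Agent '%s' appears with two units.", fit_a$agent),
          class = "chousyn_unit_error")
  }
  cb <- with_stage("combination",
                   assess_combination(fit_a, fit_b, fit_combo,
                                      ratio_fractions, levels, config))
  inform(sprintf("combine: %s + %s, %d effect level(s): %s.",
                 cb$agent_a, cb$agent_b, nrow(cb$points),
                 paste(cb$points$label, collapse = ", ")))
  attr(cb, "manifest") <- run_manifest("combine", config)
  if (!is.null(out)) {
    write_report(list(fits = list(fit_a, fit_b), combinations = list(cb)),
                 out, config = config)
  }
  if (!is.null(out_csv)) write_ci_table_csv(cb$points, out_csv)
  cb
}

#' Simulate stage: generate a synthetic study bundle
#'
#' Reads a study specification (a JSON file or an equivalent list):
#' fields `agents` (list of [agent_spec()] argument sets),
#' `doses_per_agent` (named list of dose vectors), `timepoints`,
#' `noise_sd`, `replicates`, `seed` and optional `combination`
#' (`ratio_fractions`, `interaction` = `"loewe"` or `{Dm, m}`,
#' `total_doses`). Writes one trace CSV per agent (plus one for the
#' mixture) and a manifest.
#'
#' @param spec Path to a JSON spec or a list with the fields above.
#' @param out_dir Directory for the CSV bundle.
#' @return Invisibly, a named character vector of written files (the
#'   manifest last).
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    spec_path <- spec
    spec <- jsonlite::read_json(spec, simplifyVector = TRUE)
  } else {
    spec_path <- character()
  }
  for (field in c("agents", "doses_per_agent", "seed")) {
    if (is.null(spec[[field]])) {
      abort(sprintf("Study spec is missing field '%s'.", field),
            class = "chousyn_validation_error")
    }
  }
  noise_sd <- spec$noise_sd %||% 0
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "chousyn_validation_error")
  }
  timepoints <- spec$timepoints %||% 0:5
  replicates <- spec$replicates %||% 2L
  seed <- as.integer(spec$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  n_agents <- if (is.data.frame(spec$agents)) nrow(spec$agents)
              else length(spec$agents)
  agent_specs <- lapply(seq_len(n_agents), function(i) {
    a <- as.list(if (is.data.frame(spec$agents)) spec$agents[i, ]
                 else spec$agents[[i]])
    do.call(agent_spec, a)
  })
  names(agent_specs) <- map_chr_(agent_specs, "agent")
  files <- character()
  for (i in seq_along(agent_specs)) {
    sp <- agent_specs[[i]]
    doses <- unlist(spec$doses_per_agent[[sp$agent]])
    if (is.null(doses)) {
      abort(sprintf("No doses listed for agent '%s'.", sp$agent),
            class = "chousyn_validation_error")
    }
    traces <- simulate_single_agent_study(sp, doses, timepoints, noise_sd,
                                          replicates, seed = seed + i)
    path <- file.path(out_dir, paste0("traces_", sp$agent, ".csv"))
    readr::write_csv(traces, path)
    files[sp$agent] <- path
  }
  if (!is.null(spec$combination)) {
    cmb <- spec$combination
    interaction <- cmb$interaction %||% "loewe"
    if (is.data.frame(interaction)) interaction <- as.list(interaction)
    traces <- simulate_combination_study(
      agent_specs[[1]], agent_specs[[2]],
      ratio_fractions = unlist(cmb$ratio_fractions),
      interaction = interaction,
      total_doses = unlist(cmb$total_doses),
      timepoints = timepoints, noise_sd = noise_sd,
      replicates = replicates, seed = seed + length(agent_specs) + 1L)
    path <- file.path(out_dir, "traces_combination.csv")
    readr::write_csv(traces, path)
    files["combination"] <- path
  }
  cfg <- study_config(seed = seed)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- run_manifest("simulate", cfg, spec_path)
  manifest$spec <- spec
  manifest$files <- as.list(basename(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), manifest_path)
  files["manifest"] <- manifest_path
  invisible(files)
}

map_chr_ <- function(x, field) vapply(x, function(e) e[[field]], character(1))

#' Score-plants stage: docking-score aggregation and ranking
#'
#' @param scores Path to the per-compound scores CSV or a tibble
#'   (`plant`, `compound_id`, `xp_gscore`).
#' @param totals Path to the per-plant totals CSV or a tibble (`plant`,
#'   `total_in_database`).
#' @param hit_threshold Score cutoff for [select_hits()].
#' @param out Optional JSON report path.
#' @param out_csv Optional ranking CSV path.
#' @return The ranked tibble from [rank_plants()].
#' @export
run_score_plants <- function(scores, totals, hit_threshold,
                             out = NULL, out_csv = NULL) {
  inputs <- character()
  if (is.character(scores)) {
    inputs <- c(scores, if (is.character(totals)) totals)
    loaded <- with_stage("dataio", read_docking_csv(scores, totals))
    scores <- loaded$scores
    totals <- loaded$totals
  }
  ranked <- with_stage("screening_scores", {
    rank_plants(plant_score(scores, totals, hit_threshold))
  })
  inform(sprintf("score-plants: %d plant(s), threshold %g; top: %s (%g).",
                 nrow(ranked), hit_threshold, ranked$plant[1],
                 ranked$score[1]))
  if (!is.null(out_csv)) readr::write_csv(ranked, out_csv)
  if (!is.null(out)) {
    cfg <- study_config()
    payload <- list(ranking = ranked, hit_threshold = hit_threshold,
                    manifest = run_manifest("score_plants", cfg, inputs))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = TRUE), out)
  }
  ranked
}
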