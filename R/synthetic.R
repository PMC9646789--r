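#' Specify a synthetic inhibitor
#'
#' Generative counterpart of a median-effect fit: an agent whose true
#' dose-effect behaviour is `fa/fu = (D/Dm)^m`, read out through a
#' DCIP-type declining absorbance trace whose velocity is scaled by
#' `1 - fa`.
#'
#' @param agent Label.
#' @param Dm True median-effect dose (> 0) in `unit`.
#' @param m True median-effect slope (> 0).
#' @param unit Dose unit label.
#' @param control_velocity Uninhibited velocity in delta-A/min; negative
#'   for a declining read (default -0.01, a typical well-behaved DCIP
#'   assay slope).
#' @param a0 Initial absorbance (default 1).
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(agent, Dm, m, unit = "nM",
                       control_velocity = -0.01, a0 = 1) {
  if (!is.numeric(Dm) || Dm <= 0) {
    abort("`Dm` must be > 0.", class = "chousyn_domain_error")
  }
  if (!is.numeric(m) || m <= 0) {
    abort("`m` must be > 0.", class = "chousyn_domain_error")
  }
  if (!is.numeric(control_velocity) || control_velocity >= 0) {
    abort("`control_velocity` must be negative (declining read).",
          class = "chousyn_domain_error")
  }
  structure(list(agent = agent, Dm = Dm, m = m, unit = unit,
                 control_velocity = control_velocity, a0 = a0),
            class = "agent_spec")
}

as_medfit <- function(spec) {
  medfit(spec$agent, Dm = spec$Dm, m = spec$m, dose_unit = spec$unit)
}

true_fa <- function(spec, dose) {
  ifelse(dose == 0, 0, {
    ratio <- (dose / spec$Dm)^spec$m
    ratio / (1 + ratio)
  })
}

#' Simulate one kinetic trace
#'
#' Generates a single well's absorbance-time read: the velocity is the
#' control velocity scaled by the unaffected fraction,
#' `v(D) = control_velocity * (1 - fa(D))` with fa from the median-effect
#' law (fa = 0 at dose 0), and
#' `a600(t) = a0 + v t + N(0, noise_sd)` independently per timepoint.
#' Noise lives on the measured absorbance, not on fa, so it propagates
#' through slope fitting exactly as in the real assay.
#'
#' @param spec An [agent_spec()].
#' @param dose Dose >= 0 (0 = control well).
#' @param timepoints Read times in minutes (default 0:5, a 5-minute read
#'   at one-minute intervals).
#' @param noise_sd Gaussian absorbance noise SD (>= 0).
#' @param replicate Replicate index recorded in the trace.
#' @param seed Optional integer; when supplied the RNG is seeded so the
#'   trace is fully reproducible. When `NULL` the current RNG stream is
#'   used (so that study-level simulators control one stream).
#' @return A trace tibble in the [read_trace_csv()] schema.
#' @export
simulate_trace <- function(spec, dose, timepoints = 0:5, noise_sd = 0,
                           replicate = 1L, seed = NULL) {
  stopifnot(inherits(spec, "agent_spec"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    abort("`dose` must be a single dose >= 0.",
          class = "chousyn_domain_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "chousyn_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  v <- spec$control_velocity * (1 - true_fa(spec, dose))
  a <- spec$a0 + v * timepoints +
    if (noise_sd > 0) stats::rnorm(length(timepoints), 0, noise_sd) else 0
  tibble(time_min = as.numeric(timepoints), a600 = a, agent = spec$agent,
         dose = dose, dose_unit = spec$unit,
         replicate = as.integer(replicate), is_control = dose == 0)
}

#' Simulate a single-agent dose-series study
#'
#' A full assay batch: control wells (dose 0) plus each dose, each with
#' the requested number of replicates, all driven by one seed so the
#' whole batch is byte-reproducible.
#'
#' @param spec An [agent_spec()].
#' @param doses Positive doses.
#' @param timepoints,noise_sd As in [simulate_trace()].
#' @param replicates Wells per dose (default 2, the usual duplicate
#'   design).
#' @param seed Integer seed for the whole batch.
#' @return A trace tibble ready for [build_dose_effect()].
#' @export
simulate_single_agent_study <- function(spec, doses, timepoints = 0:5,
                                        noise_sd = 0, replicates = 2L,
                                        seed = 1L) {
  stopifnot(inherits(spec, "agent_spec"))
  if (any(doses <= 0)) {
    abort("`doses` must all be > 0 (controls are generated automatically).",
          class = "chousyn_domain_error")
  }
  if (replicates < 1L) {
    abort("`replicates` must be >= 1.", class = "chousyn_domain_error")
  }
  set.seed(seed)
  grid <- expand.grid(dose = c(0, sort(doses)), replicate = seq_len(replicates))
  grid <- grid[order(grid$dose, grid$replicate), ]
  pmap(grid, function(dose, replicate) {
    simulate_trace(spec, dose, timepoints, noise_sd, replicate)
  }) |> list_rbind()
}

#' Simulate a fixed-ratio combination study
#'
#' Generates mixture traces at a series of total doses split between two
#' agents at fixed ratio fractions. Under `interaction = "loewe"` the
#' effect at each total dose is the exact Loewe-additive solution
#' ([solve_loewe_mixture()]), so the downstream CI is 1 at every level —
#' the additivity null. Alternatively an explicit mixture behaviour
#' `list(Dm = , m = )` applies the median-effect law directly to the
#' total dose, letting departures from additivity (synergy or antagonism)
#' be injected.
#'
#' @param spec_a,spec_b [agent_spec()]s for the components.
#' @param ratio_fractions Length-2 fractions of total dose summing to 1.
#' @param interaction `"loewe"` or a list with elements `Dm` and `m`.
#' @param total_doses Positive total mixture doses.
#' @param timepoints,noise_sd,replicates,seed As in
#'   [simulate_single_agent_study()].
#' @param label Agent label for the mixture traces (default
#'   `"A + B"` built from the component labels).
#' @return A trace tibble (controls included) whose dose column is the
#'   total mixture dose.
#' @export
simulate_combination_study <- function(spec_a, spec_b, ratio_fractions,
                                       interaction = "loewe",
                                       total_doses,
                                       timepoints = 0:5, noise_sd = 0,
                                       replicates = 2L, seed = 1L,
                                       label = NULL) {
  stopifnot(inherits(spec_a, "agent_spec"), inherits(spec_b, "agent_spec"))
  check_ratio(ratio_fractions)
  if (any(total_doses <= 0)) {
    abort("`total_doses` must all be > 0.", class = "chousyn_domain_error")
  }
  label <- label %||% paste(spec_a$agent, "+", spec_b$agent)
  fa_at <- if (identical(interaction, "loewe")) {
    fit_a <- as_medfit(spec_a); fit_b <- as_medfit(spec_b)
    function(total) solve_loewe_mixture(fit_a, fit_b, ratio_fractions, total)
  } else if (is.list(interaction) &&
             all(c("Dm", "m") %in% names(interaction))) {
    function(total) {
      ratio <- (total / interaction$Dm)^interaction$m
      ratio / (1 + ratio)
    }
  } else {
    abort("`interaction` must be \"loewe\" or list(Dm = , m = ).",
          class = "chousyn_validation_error")
  }
  mix_spec <- structure(
    list(agent = label, Dm = 1, m = 1, unit = "mixture",
         control_velocity = spec_a$control_velocity, a0 = spec_a$a0),
    class = "agent_spec")
  set.seed(seed)
  rows <- list()
  for (rep in seq_len(replicates)) {
    rows[[length(rows) + 1L]] <-
      simulate_trace(mix_spec, 0, timepoints, noise_sd, rep)
  }
  for (total in sort(total_doses)) {
    fa <- fa_at(total)
    v <- mix_spec$control_velocity * (1 - fa)
    for (rep in seq_len(replicates)) {
      a <- mix_spec$a0 + v * timepoints +
        if (noise_sd > 0) stats::rnorm(length(timepoints), 0, noise_sd) else 0
      rows[[length(rows) + 1L]] <- tibble(
        time_min = as.numeric(timepoints), a600 = a, agent = label,
        dose = total, dose_unit = "mixture", replicate = as.integer(rep),
        is_control = FALSE)
    }
  }
  list_rbind(rows)
}
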