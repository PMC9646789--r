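#' Estimate reaction velocity from one kinetic trace
#'
#' The assay readout is a linear decline in absorbance (DCIP reduction at
#' 600 nm); the reaction velocity is the ordinary-least-squares slope of
#' absorbance on time, in absorbance units per minute. `mode = "full"`
#' regresses over every timepoint — appropriate for the standard short
#' linear read. `mode = "auto"` picks the contiguous window of length at
#' least `max(3, n/2)` with the highest r-squared, for traces whose early
#' or late points drift off the linear phase; ties are broken in favour of
#' the earlier, then the longer, window.
#'
#' @param trace A data frame for a single well with numeric columns
#'   `time_min` (strictly increasing) and `a600`.
#' @param mode `"full"` or `"auto"`.
#' @return A one-row tibble: `slope` (delta-A per minute), `intercept`,
#'   `r_squared`, `window_start`, `window_end` (indices into the trace),
#'   `n_used`.
#' @examples
#' tr <- tibble::tibble(time_min = 0:5, a600 = 1 - 0.01 * (0:5))
#' fit_velocity(tr)$slope
#' @export
fit_velocity <- function(trace, mode = c("full", "auto")) {
  mode <- match.arg(mode)
  t <- trace$time_min
  y <- trace$a600
  n <- length(t)
  if (n < 3L) {
    abort(sprintf("Velocity fit needs at least 3 timepoints, got %d.", n),
          class = "chousyn_insufficient_data_error")
  }
  if (any(diff(t) <= 0)) {
    abort("Trace times must be strictly increasing.",
          class = "chousyn_validation_error")
  }
  if (mode == "full") {
    best <- ols_window(t, y, 1L, n)
  } else {
    min_len <- max(3L, ceiling(n / 2))
    best <- NULL
    for (len in min_len:n) {
      for (start in 1:(n - len + 1L)) {
        cand <- ols_window(t, y, start, start + len - 1L)
        if (is.null(best) ||
            cand$r_squared > best$r_squared + 1e-12 ||
            (abs(cand$r_squared - best$r_squared) <= 1e-12 &&
             (cand$window_start < best$window_start ||
              (cand$window_start == best$window_start &&
               cand$n_used > best$n_used)))) {
          best <- cand
        }
      }
    }
  }
  as_tibble(best)
}

ols_window <- function(t, y, i0, i1) {
  tw <- t[i0:i1]; yw <- y[i0:i1]
  slope <- stats::cov(tw, yw) / stats::var(tw)
  intercept <- mean(yw) - slope * mean(tw)
  tss <- sum((yw - mean(yw))^2)
  rss <- sum((yw - intercept - slope * tw)^2)
  # a flat (zero-variance) segment is fitted exactly by slope 0
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(yw^2))) 1 else {
    max(0, min(1, 1 - rss / tss))
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       window_start = i0, window_end = i1, n_used = i1 - i0 + 1L)
}

#' Percent inhibition from control and sample velocities
#'
#' Enzyme activity is read as the velocity of absorbance decline; percent
#' inhibition compares a treated well's velocity against the uninhibited
#' enzyme control:
#' `inhibition(%) = (slope_control - slope_sample) / slope_control * 100`.
#' Values below 0 (apparent activation) or above 100 are returned as
#' computed — clamping would hide assay problems — with a warning.
#'
#' @param slope_control Velocity of the enzyme control (delta-A/min,
#'   non-zero; negative for a DCIP-type declining read).
#' @param slope_sample Velocity (or vector of velocities) of treated
#'   wells.
#' @return Numeric percent inhibition, same length as `slope_sample`.
#' @examples
#' percent_inhibition(-0.010, -0.004) # 60
#' @export
percent_inhibition <- function(slope_control, slope_sample) {
  if (!is.numeric(slope_control) || length(slope_control) != 1L ||
      is.na(slope_control) || slope_control == 0) {
    abort("`slope_control` must be a single non-zero velocity.",
          class = "chousyn_undefined_control_error")
  }
  out <- (slope_control - slope_sample) / slope_control * 100
  n_out <- sum(out < 0 | out > 100, na.rm = TRUE)
  if (n_out > 0) {
    warn(sprintf("%d inhibition value(s) outside [0, 100]%%; returned as computed.",
                 n_out))
  }
  out
}

#' Build a dose-effect table from kinetic traces
#'
#' The full readout chain: per-well velocities, replicate-averaged slopes
#' per (agent, dose), percent inhibition against the mean control
#' velocity, and finally the fraction affected `fa = inhibition / 100`.
#' Slopes are averaged before computing inhibition (not the other way
#' round), matching a velocity estimated from the pooled linear region.
#' Controls are matched per agent where agent-labelled control wells
#' exist, otherwise all control wells in the batch are pooled.
#'
#' @param traces A trace tibble as returned by [read_trace_csv()] or
#'   [simulate_single_agent_study()].
#' @param config A [study_config()]; supplies the velocity window policy
#'   and the fa clip bounds for the `fittable` flag.
#' @return A dose-effect tibble (`agent`, `dose`, `dose_unit`, `fa`,
#'   `n_replicates`, `fittable`) ready for [fit_median_effect()].
#' @export
build_dose_effect <- function(traces, config = NULL) {
  config <- as_config(config)
  if (!any(traces$is_control)) {
    abort("No control trace (is_control = TRUE) in the collection.",
          class = "chousyn_missing_control_error")
  }
  wells <- traces |>
    tidyr::nest(trace = c("time_min", "a600")) |>
    mutate(slope = map_dbl(.data$trace,
                           ~ fit_velocity(.x, config$velocity_window)$slope))

  ctrl <- filter(wells, .data$is_control)
  ctrl_slope_for <- function(agent) {
    own <- ctrl$slope[ctrl$agent == agent]
    if (length(own)) mean(own) else mean(ctrl$slope)
  }
  samples <- wells |>
    filter(!.data$is_control) |>
    group_by(.data$agent, .data$dose, .data$dose_unit) |>
    summarise(mean_slope = mean(.data$slope), n_replicates = n(),
              .groups = "drop")
  out <- samples |>
    mutate(
      fa = map_dbl(seq_len(n()), function(i) {
        sc <- ctrl_slope_for(samples$agent[i])
        suppressWarnings(percent_inhibition(sc, samples$mean_slope[i])) / 100
      })
    ) |>
    select("agent", "dose", "dose_unit", "fa", "n_replicates")
  flag_fittable(out, config)
}
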