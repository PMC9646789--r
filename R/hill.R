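#' Four-parameter logistic (Hill) dose-response fit
#'
#' The nonlinear-regression route to IC50, complementing the linearized
#' median-effect fit. The model on the percent-inhibition scale is
#' `inhibition(%) = bottom + (top - bottom) / (1 + (ic50 / D)^hill_slope)`.
#' By default `bottom` and `top` are fixed at 0 and 100 (two free
#' parameters), under which the 4PL and the median-effect model coincide:
#' ic50 equals Dm and the Hill slope equals m. Releasing the asymptotes
#' fits all four parameters and needs at least 5 points.
#'
#' Fitting is Levenberg-Marquardt least squares with multiple starts
#' (a median-effect-based guess plus dose quartiles); the `converged` flag
#' reports the optimizer's own status honestly.
#'
#' @param points A dose-effect tibble for a single agent.
#' @param fix_bottom,fix_top Numeric to fix an asymptote (default 0 and
#'   100), or `NA` to free it.
#' @param config A [study_config()].
#' @return A `hillfit`: `agent`, `ic50`, `hill_slope`, `bottom`, `top`,
#'   `converged`, `rss`, `n_points`, `dose_unit`.
#' @seealso [fit_median_effect()]
#' @export
fit_hill <- function(points, fix_bottom = 0, fix_top = 100, config = NULL) {
  config <- as_config(config)
  if (!"fittable" %in% names(points)) points <- flag_fittable(points, config)
  use <- filter(points, .data$fittable)
  n_free <- 2L + is.na(fix_bottom) + is.na(fix_top)
  n_min <- if (n_free > 2L) 5L else 3L
  if (nrow(use) < n_min) {
    abort(sprintf(
      "Hill fit with %d free parameter(s) needs >= %d fittable points, got %d.",
      n_free, n_min, nrow(use)),
      class = "chousyn_insufficient_data_error")
  }
  agent <- unique(use$agent)
  if (length(agent) != 1L) {
    abort("Hill fit expects a single agent.",
          class = "chousyn_validation_error")
  }
  dose <- use$dose
  inh <- use$fa * 100

  # starts: median-effect guess where obtainable, then dose quartiles
  ic50_starts <- unname(stats::quantile(dose, c(0.25, 0.5, 0.75)))
  slope_starts <- c(1, 2)
  me_guess <- tryCatch(fit_median_effect(use, config), error = function(e) NULL)
  if (!is.null(me_guess) && is.finite(me_guess$Dm) && me_guess$Dm > 0 &&
      me_guess$m > 0) {
    ic50_starts <- c(me_guess$Dm, ic50_starts)
    slope_starts <- c(me_guess$m, slope_starts)
  }
  starts <- expand.grid(ic50 = unique(ic50_starts),
                        hill_slope = unique(slope_starts))

  model_rss <- function(p) {
    bottom <- if (is.na(fix_bottom)) p[["bottom"]] else fix_bottom
    top <- if (is.na(fix_top)) p[["top"]] else fix_top
    pred <- bottom + (top - bottom) / (1 + (p[["ic50"]] / dose)^p[["hill_slope"]])
    sum((inh - pred)^2)
  }

  bterm <- if (is.na(fix_bottom)) "bottom" else format(fix_bottom)
  tterm <- if (is.na(fix_top)) "top" else format(fix_top)
  form <- stats::as.formula(sprintf(
    "inh ~ %s + (%s - %s) / (1 + (ic50 / dose)^hill_slope)",
    bterm, tterm, bterm))
  lower <- c(ic50 = 1e-12, hill_slope = 1e-6,
             if (is.na(fix_bottom)) c(bottom = -Inf),
             if (is.na(fix_top)) c(top = -Inf))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(ic50 = starts$ic50[i], hill_slope = starts$hill_slope[i])
    if (is.na(fix_bottom)) start$bottom <- min(inh)
    if (is.na(fix_top)) start$top <- max(inh)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = list(inh = inh, dose = dose), start = start,
        lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    abort(sprintf("Hill fit for '%s' failed to converge from any start.",
                  agent), class = "chousyn_convergence_error")
  }
  p <- coef(best$fit)
  bottom <- if (is.na(fix_bottom)) unname(p[["bottom"]]) else fix_bottom
  top <- if (is.na(fix_top)) unname(p[["top"]]) else fix_top
  if (bottom >= top) {
    abort(sprintf("Hill fit for '%s' is degenerate: bottom >= top.", agent),
          class = "chousyn_convergence_error")
  }
  structure(
    list(agent = agent, ic50 = unname(p[["ic50"]]),
         hill_slope = unname(p[["hill_slope"]]),
         bottom = bottom, top = top,
         converged = isTRUE(best$converged), rss = best$rss,
         n_points = nrow(use), dose_unit = unique(use$dose_unit)),
    class = "hillfit")
}

#' @export
print.hillfit <- function(x, ...) {
  cat(sprintf("<Hill (4PL) fit: %s>\n", x$agent))
  cat(sprintf("  IC50 = %g %s   slope = %g   [%g, %g]   rss = %.4g%s\n",
              x$ic50, x$dose_unit, x$hill_slope, x$bottom, x$top, x$rss,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @rdname fit_hill
#' @param x,object A `hillfit`.
#' @param ... Unused.
#' @method tidy hillfit
#' @export
tidy.hillfit <- function(x, ...) {
  tibble(agent = x$agent,
         term = c("ic50", "hill_slope", "bottom", "top"),
         estimate = c(x$ic50, x$hill_slope, x$bottom, x$top),
         unit = c(x$dose_unit, "", "%", "%"))
}

#' @rdname fit_hill
#' @method glance hillfit
#' @export
glance.hillfit <- function(x, ...) {
  tibble(agent = x$agent, ic50 = x$ic50, hill_slope = x$hill_slope,
         bottom = x$bottom, top = x$top, rss = x$rss,
         converged = x$converged, n_points = x$n_points)
}
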