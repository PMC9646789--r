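#' Fit the median-effect model to a dose-effect table
#'
#' The mass-action median-effect equation relates dose D to the fraction
#' affected fa through `fa/fu = (D/Dm)^m` with `fu = 1 - fa`, where Dm is
#' the median-effect dose (the dose giving 50% effect, equivalent to IC50
#' or ED50) and m the sigmoidicity of the dose-effect curve. Taking logs
#' gives a straight line, the median-effect plot:
#' `log(fa/fu) = m log(D) - m log(Dm)`,
#' so the parameters come from ordinary least squares of `y = log(fa/fu)`
#' on `x = log(D)`: m is the slope, Dm the antilog of the x-intercept, and
#' r the Pearson correlation of the transformed points, which measures how
#' well the data conform to mass action (conventionally r > 0.97 for
#' in vitro enzyme systems).
#'
#' Only points flagged fittable (dose > 0, fa strictly inside the clip
#' bounds) enter the regression; points at or near fa of 0 or 1 are
#' excluded because the transform is undefined or ill-conditioned there.
#' The regression is unweighted.
#'
#' @param points A dose-effect tibble (`agent`, `dose`, `dose_unit`, `fa`,
#'   optionally `fittable`) for a single agent.
#' @param config A [study_config()]; supplies clip bounds and the plot's
#'   log base (slope and r are base-invariant, Dm is base-consistent).
#' @return A `medfit` object: fields `agent`, `Dm` (agent units), `m`
#'   (dimensionless), `r`, `n_points`, `dose_unit`, plus the regression
#'   `intercept` and the transformed `data` used.
#' @examples
#' pts <- tibble::tibble(agent = "breq", dose = c(10, 30),
#'                       dose_unit = "nM", fa = c(0.5, 0.75))
#' fit <- fit_median_effect(pts)
#' c(fit$Dm, fit$m) # 10, 1
#' @seealso [effect_at_dose()], [dose_for_effect()], [fit_hill()]
#' @export
fit_median_effect <- function(points, config = NULL) {
  config <- as_config(config)
  if (!"fittable" %in% names(points)) {
    points <- flag_fittable(points, config)
  }
  agents <- unique(points$agent)
  if (length(agents) != 1L) {
    abort(sprintf("Expected a single agent, got: %s.",
                  paste(agents, collapse = ", ")),
          class = "chousyn_validation_error")
  }
  units <- unique(points$dose_unit)
  if (length(units) != 1L) {
    abort(sprintf("Agent '%s' uses mixed dose units: %s.", agents,
                  paste(units, collapse = ", ")),
          class = "chousyn_unit_error")
  }
  use <- filter(points, .data$fittable)
  if (nrow(use) < 2L) {
    abort(sprintf(
      "Median-effect fit for '%s' needs >= 2 fittable points, got %d.",
      agents, nrow(use)), class = "chousyn_insufficient_data_error")
  }
  if (length(unique(use$dose)) < 2L) {
    abort(sprintf("All fittable doses for '%s' are equal; design is degenerate.",
                  agents), class = "chousyn_degenerate_design_error")
  }
  b <- config$log_base
  x <- log(use$dose, base = b)
  y <- log(use$fa / (1 - use$fa), base = b)
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- suppressWarnings(cor(x, y))
  structure(
    list(agent = agents, Dm = b^(-intercept / m), m = m, r = r,
         n_points = nrow(use), dose_unit = units,
         intercept = intercept, log_base = b,
         data = tibble(dose = use$dose, fa = use$fa, x = x, y = y)),
    class = "medfit")
}

#' Construct a median-effect fit from known parameters
#'
#' For working with published (Dm, m) parameter tables when the raw
#' dose-effect measurements behind them are unavailable.
#'
#' @param agent Agent label.
#' @param Dm Median-effect dose, > 0, in `dose_unit`.
#' @param m Median-effect slope, > 0 for an inhibitor.
#' @param r Linear correlation of the original plot (optional, `NA` if
#'   unknown).
#' @param dose_unit Unit label carried through reports.
#' @param n_points Number of points behind the published fit, if known.
#' @return A `medfit` object.
#' @export
medfit <- function(agent, Dm, m, r = NA_real_, dose_unit = "",
                   n_points = NA_integer_) {
  if (!is.numeric(Dm) || length(Dm) != 1L || is.na(Dm) || Dm <= 0) {
    abort("`Dm` must be a single positive dose.",
          class = "chousyn_validation_error")
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) {
    abort("`m` must be a single finite slope.",
          class = "chousyn_validation_error")
  }
  structure(
    list(agent = agent, Dm = as.numeric(Dm), m = as.numeric(m),
         r = as.numeric(r), n_points = n_points, dose_unit = dose_unit,
         intercept = -m * log10(Dm), log_base = 10, data = NULL),
    class = "medfit")
}

#' Predicted fraction affected at a dose
#'
#' Inverts the fitted median-effect plot back to the effect scale:
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`, strictly increasing in dose for
#' m > 0, with `fa = 0.5` at `D = Dm` by construction.
#'
#' @param fit A `medfit`.
#' @param dose Dose(s), > 0, in the fit's unit.
#' @return Fraction(s) affected in (0, 1).
#' @export
effect_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "medfit"))
  if (any(!is.finite(dose) | dose <= 0)) {
    abort("`dose` must be positive.", class = "chousyn_domain_error")
  }
  ratio <- (dose / fit$Dm)^fit$m
  ratio / (1 + ratio)
}

#' Dose required for a target effect level
#'
#' The inverse of [effect_at_dose()]:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)` — the single-agent dose producing the
#' x-effect level, the quantity the combination index and dose-reduction
#' index are built from.
#'
#' @param fit A `medfit`.
#' @param fa Target fraction(s) affected, strictly inside (0, 1).
#' @return Dose(s) in the fit's unit.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "medfit"))
  if (any(!is.finite(fa) | fa <= 0 | fa >= 1)) {
    abort("`fa` must lie strictly inside (0, 1).",
          class = "chousyn_domain_error")
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Median-effect plot coordinates
#'
#' Transforms fittable dose-effect points into the linearized plot
#' coordinates `x = log(D)`, `y = log(fa/fu)` for plotting layers.
#'
#' @param points A dose-effect tibble (one or more agents).
#' @param config A [study_config()] (log base, clip bounds).
#' @return A tibble `agent`, `dose`, `fa`, `x`, `y` with only fittable
#'   points.
#' @export
median_effect_points <- function(points, config = NULL) {
  config <- as_config(config)
  if (!"fittable" %in% names(points)) points <- flag_fittable(points, config)
  use <- filter(points, .data$fittable)
  b <- config$log_base
  mutate(select(use, "agent", "dose", "fa"),
         x = log(.data$dose, base = b),
         y = log(.data$fa / (1 - .data$fa), base = b))
}

#' @export
print.medfit <- function(x, ...) {
  cat(sprintf("<median-effect fit: %s>\n", x$agent))
  cat(sprintf("  Dm = %g %s   m = %g   r = %s   (n = %s)\n",
              x$Dm, x$dose_unit, x$m,
              ifelse(is.na(x$r), "NA", format(x$r)),
              ifelse(is.na(x$n_points), "?", x$n_points)))
  invisible(x)
}

#' @rdname fit_median_effect
#' @param x,object A `medfit`.
#' @param ... Unused.
#' @method tidy medfit
#' @export
tidy.medfit <- function(x, ...) {
  tibble(agent = x$agent,
         term = c("Dm", "m"),
         estimate = c(x$Dm, x$m),
         unit = c(x$dose_unit, ""))
}

#' @rdname fit_median_effect
#' @method glance medfit
#' @export
glance.medfit <- function(x, ...) {
  tibble(agent = x$agent, Dm = x$Dm, m = x$m, r = x$r,
         n_points = x$n_points, dose_unit = x$dose_unit)
}

#' @rdname fit_median_effect
#' @method autoplot medfit
#' @export
autoplot.medfit <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This medfit carries no underlying points to plot.",
          class = "chousyn_validation_error")
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$m,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("Median-effect plot: %s", object$agent),
      subtitle = sprintf("Dm = %.4g %s, m = %.4g, r = %.5f",
                         object$Dm, object$dose_unit, object$m, object$r),
      x = sprintf("log%g(dose)", object$log_base),
      y = sprintf("log%g(fa / fu)", object$log_base)) +
    ggplot2::theme_minimal()
}
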