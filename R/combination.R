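#' Combination index at an effect level
#'
#' The Chou-Talalay combination index in its two-term (mutually
#' exclusive) form:
#' `CI = Da / (Dx)a + Db / (Dx)b`,
#' where Da, Db are the component doses applied in combination and
#' (Dx)a, (Dx)b the single-agent doses producing the same effect level fa
#' (from each agent's median-effect fit). CI < 1 indicates synergism,
#' CI = 1 additivity (the Loewe line), CI > 1 antagonism. CI is unitless:
#' each dose is divided by an equipotent dose in the same unit, so agents
#' measured in different units combine without conversion.
#'
#' @param dose_a,dose_b Component doses (>= 0, not both zero), each in its
#'   own agent's unit.
#' @param fit_a,fit_b Single-agent `medfit` objects.
#' @param fa Effect level, strictly inside (0, 1). Vectors are recycled
#'   in the usual way.
#' @return Numeric CI value(s).
#' @examples
#' a <- medfit("A", Dm = 10, m = 1)
#' b <- medfit("B", Dm = 100, m = 2)
#' combination_index(5, 50, a, b, fa = 0.5) # 1: the additivity line
#' @export
combination_index <- function(dose_a, dose_b, fit_a, fit_b, fa) {
  if (any(dose_a < 0 | dose_b < 0) || any(dose_a == 0 & dose_b == 0)) {
    abort("Doses must be >= 0 and not both zero.",
          class = "chousyn_domain_error")
  }
  dose_a / dose_for_effect(fit_a, fa) + dose_b / dose_for_effect(fit_b, fa)
}

#' Dose-reduction index
#'
#' How many fold less of a drug is needed in combination than alone for
#' the same effect: `DRI = Dx(alone) / D(in combination)` at effect level
#' fa. DRI > 1 means a favourable dose reduction.
#'
#' @param fit The agent's `medfit`.
#' @param dose_in_combo The agent's dose within the combination (> 0).
#' @param fa Effect level in (0, 1).
#' @return Numeric DRI value(s).
#' @export
dose_reduction_index <- function(fit, dose_in_combo, fa) {
  if (any(!is.finite(dose_in_combo) | dose_in_combo <= 0)) {
    abort("`dose_in_combo` must be > 0.", class = "chousyn_domain_error")
  }
  dose_for_effect(fit, fa) / dose_in_combo
}

#' Combination index from a pair of dose-reduction indices
#'
#' Algebraic identity linking the two statistics: since
#' `DRI_a = (Dx)a / Da` and `DRI_b = (Dx)b / Db`,
#' `CI = 1/DRI_a + 1/DRI_b` exactly. Useful for recomputing CI from
#' published DRI tables when the underlying doses are not printed.
#'
#' @param dri_a,dri_b Dose-reduction indices (> 0).
#' @return Numeric CI value(s).
#' @examples
#' ci_from_dri(4.38, 4.08) # 0.473...
#' @export
ci_from_dri <- function(dri_a, dri_b) {
  if (any(!is.finite(dri_a) | dri_a <= 0) ||
      any(!is.finite(dri_b) | dri_b <= 0)) {
    abort("DRI values must be positive.", class = "chousyn_domain_error")
  }
  1 / dri_a + 1 / dri_b
}

#' Classify an interaction from its combination index
#'
#' Labels CI values using an additive band around 1: additive when
#' `|CI - 1| <= additive_band`, synergism below the band, antagonism
#' above. A strict CI = 1 rule is never met by measured data, so the band
#' half-width (default 0.05) makes the printed-table convention explicit.
#'
#' @param ci Combination index value(s), > 0.
#' @param additive_band Half-width of the additive band (>= 0).
#' @return Character vector: `"synergism"`, `"additive"` or
#'   `"antagonism"`.
#' @export
classify_interaction <- function(ci, additive_band = 0.05) {
  if (any(!is.finite(ci) | ci <= 0)) {
    abort("`ci` must be positive.", class = "chousyn_domain_error")
  }
  # tiny slack so band edges are inclusive despite binary rounding
  dplyr::case_when(
    abs(ci - 1) <= additive_band + 1e-9 ~ "additive",
    ci < 1 ~ "synergism",
    .default = "antagonism"
  )
}

#' Normalized isobologram coordinates
#'
#' Dose-normalized isobologram: each combination dose pair is mapped to
#' `(Da/(Dx)a, Db/(Dx)b)` so that the additivity line joins (1, 0) and
#' (0, 1) for every effect level. Points below the line (coordinate sum
#' < 1) indicate synergism, on it additivity, above it antagonism; the
#' side-of-line call uses the same additive band as
#' [classify_interaction()] and therefore always agrees with it.
#'
#' @inheritParams combination_index
#' @param additive_band Half-width of the additive band on the coordinate
#'   sum.
#' @return A tibble: `fa`, `x` (= Da/(Dx)a), `y` (= Db/(Dx)b), `side`
#'   (`"below"`, `"on"`, `"above"`).
#' @export
isobologram_point <- function(dose_a, dose_b, fit_a, fit_b, fa,
                              additive_band = 0.05) {
  if (any(dose_a < 0 | dose_b < 0) || any(dose_a == 0 & dose_b == 0)) {
    abort("Doses must be >= 0 and not both zero.",
          class = "chousyn_domain_error")
  }
  x <- dose_a / dose_for_effect(fit_a, fa)
  y <- dose_b / dose_for_effect(fit_b, fa)
  s <- x + y
  tibble(fa = fa, x = x, y = y,
         side = dplyr::case_when(
           abs(s - 1) <= additive_band + 1e-9 ~ "on",
           s < 1 ~ "below",
           .default = "above"))
}

#' fa-CI profile of a fixed-ratio combination
#'
#' Sweeps the combination index across effect levels for a mixture tested
#' at a fixed dose ratio. At each effect level the total mixture dose is
#' read off the mixture's own median-effect fit
#' (`Dc = dose_for_effect(fit_combo, fa)`), split into component doses by
#' the ratio fractions, and compared against each agent's single-agent
#' equipotent dose — yielding CI, both DRIs and the interaction label.
#' This is the standard construction behind fa-CI plots.
#'
#' @param fit_combo `medfit` of the mixture, fitted on the total-dose
#'   axis.
#' @param ratio_fractions Length-2 numeric summing to 1: the fraction of
#'   the total mixture dose contributed by each agent.
#' @param fit_a,fit_b Single-agent `medfit` objects.
#' @param fa_grid Effect levels to evaluate, each in (0, 1).
#' @param additive_band Half-width of the additive CI band.
#' @return A tibble of combination points: `fa`, `dose_a`, `dose_b`,
#'   `dx_a`, `dx_b`, `ci`, `dri_a`, `dri_b`, `label`.
#' @export
fa_ci_profile <- function(fit_combo, ratio_fractions, fit_a, fit_b,
                          fa_grid = seq(0.05, 0.95, by = 0.05),
                          additive_band = 0.05) {
  check_ratio(ratio_fractions)
  if (length(fa_grid) == 0L) {
    abort("`fa_grid` must be non-empty.", class = "chousyn_domain_error")
  }
  if (any(fa_grid <= 0 | fa_grid >= 1)) {
    abort("`fa_grid` values must lie strictly inside (0, 1).",
          class = "chousyn_domain_error")
  }
  dc <- dose_for_effect(fit_combo, fa_grid)
  dose_a <- ratio_fractions[1] * dc
  dose_b <- ratio_fractions[2] * dc
  dx_a <- dose_for_effect(fit_a, fa_grid)
  dx_b <- dose_for_effect(fit_b, fa_grid)
  ci <- dose_a / dx_a + dose_b / dx_b
  tibble(
    fa = fa_grid, dose_a = dose_a, dose_b = dose_b,
    dx_a = dx_a, dx_b = dx_b, ci = ci,
    dri_a = dx_a / dose_a, dri_b = dx_b / dose_b,
    label = classify_interaction(ci, additive_band))
}

#' Effect of a Loewe-additive mixture at a total dose
#'
#' Solves the Loewe additivity condition for the effect fraction of a
#' fixed-ratio mixture: the unique fa with
#' `p * Dc / Dx_a(fa) + q * Dc / Dx_b(fa) = 1`,
#' where p, q are the ratio fractions and Dc the total dose. The left
#' side is strictly decreasing in fa for positive slopes, so the root is
#' unique; it is found by Brent bracketing on fa in (1e-9, 1 - 1e-9) to
#' an absolute tolerance of 1e-10. Used to construct exact additive
#' reference mixtures (for which the CI is 1 at every level).
#'
#' @param fit_a,fit_b Single-agent `medfit` objects.
#' @param ratio_fractions Length-2 fractions summing to 1.
#' @param total_dose Total mixture dose (> 0) on the combined-dose axis.
#' @return The effect fraction fa in (0, 1).
#' @export
solve_loewe_mixture <- function(fit_a, fit_b, ratio_fractions, total_dose) {
  check_ratio(ratio_fractions)
  if (!is.numeric(total_dose) || length(total_dose) != 1L ||
      !is.finite(total_dose) || total_dose <= 0) {
    abort("`total_dose` must be a single positive dose.",
          class = "chousyn_domain_error")
  }
  p <- ratio_fractions[1]; q <- ratio_fractions[2]
  f <- function(fa) {
    p * total_dose / dose_for_effect(fit_a, fa) +
      q * total_dose / dose_for_effect(fit_b, fa) - 1
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  flo <- f(lo); fhi <- f(hi)
  if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
    abort(sprintf(
      "Loewe condition has no sign change on (%g, %g): f(lo) = %g, f(hi) = %g.",
      lo, hi, flo, fhi), class = "chousyn_solver_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Assess a fixed-ratio drug combination
#'
#' One-call combination analysis: given the two single-agent fits and the
#' mixture's fit (or the dose-effect points to produce them), computes the
#' fa-CI profile, normalized isobologram coordinates and interaction
#' labels at the requested effect levels.
#'
#' @param fit_a,fit_b Single-agent `medfit` objects.
#' @param fit_combo `medfit` of the mixture on the total-dose axis.
#' @param ratio_fractions Length-2 fractions of total dose per agent
#'   summing to 1; default is Dm-proportional (the equipotency-anchored
#'   fixed ratio `Dm_a : Dm_b`).
#' @param levels Effect levels for the per-level table (default the five
#'   canonical levels 0.1, 0.3, 0.5, 0.7, 0.9).
#' @param config A [study_config()] (additive band).
#' @return A `combo_assessment`: list with `agent_a`, `agent_b`,
#'   `ratio_fractions`, `fit_combo`, `points` (CI/DRI tibble) and
#'   `isobologram` (coordinates tibble).
#' @export
assess_combination <- function(fit_a, fit_b, fit_combo,
                               ratio_fractions = NULL,
                               levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               config = NULL) {
  config <- as_config(config)
  stopifnot(inherits(fit_a, "medfit"), inherits(fit_b, "medfit"),
            inherits(fit_combo, "medfit"))
  if (is.null(ratio_fractions)) {
    ratio_fractions <- c(fit_a$Dm, fit_b$Dm) / (fit_a$Dm + fit_b$Dm)
  }
  check_ratio(ratio_fractions)
  points <- fa_ci_profile(fit_combo, ratio_fractions, fit_a, fit_b,
                          fa_grid = levels,
                          additive_band = config$additive_band)
  iso <- isobologram_point(points$dose_a, points$dose_b, fit_a, fit_b,
                           points$fa, additive_band = config$additive_band)
  structure(
    list(agent_a = fit_a$agent, agent_b = fit_b$agent,
         ratio_fractions = ratio_fractions,
         fit_combo = fit_combo, points = points, isobologram = iso),
    class = "combo_assessment")
}

#' @export
print.combo_assessment <- function(x, ...) {
  cat(sprintf("<combination assessment: %s + %s (ratio %.3g : %.3g)>\n",
              x$agent_a, x$agent_b,
              x$ratio_fractions[1], x$ratio_fractions[2]))
  print(x$points)
  invisible(x)
}

#' @rdname assess_combination
#' @param x,object A `combo_assessment`.
#' @param ... Unused.
#' @method tidy combo_assessment
#' @export
tidy.combo_assessment <- function(x, ...) x$points

#' @rdname assess_combination
#' @method glance combo_assessment
#' @export
glance.combo_assessment <- function(x, ...) {
  tibble(agent_a = x$agent_a, agent_b = x$agent_b,
         ratio_a = x$ratio_fractions[1], ratio_b = x$ratio_fractions[2],
         combo_Dm = x$fit_combo$Dm, combo_m = x$fit_combo$m,
         n_levels = nrow(x$points),
         n_synergism = sum(x$points$label == "synergism"),
         n_additive = sum(x$points$label == "additive"),
         n_antagonism = sum(x$points$label == "antagonism"))
}

#' Plot an fa-CI profile
#'
#' Combination index against effect level with the CI = 1 additivity line
#' and the additive band shaded.
#'
#' @param points A combination-point tibble from [fa_ci_profile()].
#' @param additive_band Band half-width to shade.
#' @return A ggplot object.
#' @export
plot_fa_ci <- function(points, additive_band = 0.05) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$fa, y = .data$ci)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 1 - additive_band, ymax = 1 + additive_band,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::labs(x = "effect level (fa)", y = "combination index (CI)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a normalized isobologram
#'
#' @param iso An isobologram tibble from [isobologram_point()] or
#'   `assess_combination()$isobologram`.
#' @return A ggplot object.
#' @export
plot_isobologram <- function(iso) {
  ggplot2::ggplot(iso, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("segment", x = 1, y = 0, xend = 0, yend = 1,
                      linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$side,
                                     shape = factor(.data$fa)), size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::labs(x = "Da / (Dx)a", y = "Db / (Dx)b",
                  colour = "side of line", shape = "fa") +
    ggplot2::theme_minimal()
}

#' @method autoplot combo_assessment
#' @export
autoplot.combo_assessment <- function(object, which = c("fa_ci", "isobologram"),
                                      ...) {
  which <- match.arg(which)
  if (which == "fa_ci") plot_fa_ci(object$points)
  else plot_isobologram(object$isobologram)
}

check_ratio <- function(ratio_fractions) {
  if (!is.numeric(ratio_fractions) || length(ratio_fractions) != 2L ||
      any(!is.finite(ratio_fractions)) || any(ratio_fractions < 0) ||
      abs(sum(ratio_fractions) - 1) > 1e-8) {
    abort("`ratio_fractions` must be two non-negative numbers summing to 1.",
          class = "chousyn_domain_error")
  }
  invisible(ratio_fractions)
}
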