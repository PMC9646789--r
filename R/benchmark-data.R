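# Literature benchmark: published dose-effect and combination tables for
# four hDHODH inhibitors (brequinar, silibinin, silymarin standard
# extract, Allium sativum extract) assayed by the DCIP colorimetric
# method. Values are built in code so the package carries no binary data.

#' Benchmark single-agent dose-effect table
#'
#' Published equi-effect (ECx) doses for four hDHODH inhibitors at the
#' five canonical effect levels (10, 30, 50, 70 and 90% inhibition).
#' Brequinar and silibinin are dosed in nM, the two botanical extracts in
#' ug/ml. Note the printed ECx doses sit on a dose axis whose scale is
#' twice the corresponding published Dm values (a constant factor across
#' all agents and levels); slopes and correlations are unaffected because
#' the median-effect fit is scale-equivariant, so this table anchors m
#' and r benchmarks, not Dm.
#'
#' @return A dose-effect tibble (`agent`, `dose`, `dose_unit`, `fa`), 20
#'   rows.
#' @export
dhodh_dose_effect <- function() {
  tibble(
    agent = rep(c("brequinar", "allium_sativum", "silymarin", "silibinin"),
                each = 5),
    dose = c(3.78, 10.28, 19.54, 36.82, 101.74,
             72.42, 205.82, 403.56, 791.9, 2314.24,
             65.58, 155.38, 267.26, 459.28, 1086.42,
             27.12, 105.84, 243.76, 567.62, 2189.06),
    dose_unit = rep(c("nM", "ug/ml", "ug/ml", "nM"), each = 5),
    fa = rep(c(0.10, 0.30, 0.50, 0.70, 0.90), times = 4)
  )
}

#' Benchmark median-effect parameters
#'
#' Published dose-effect curve parameters (Dm, m, r) for the four single
#' agents and their three binary combinations with brequinar, as fitted
#' by CompuSyn from the original assay data (the raw mixture
#' measurements behind the combination rows were never published, so
#' those fits can only be consumed, not regenerated).
#'
#' @return A tibble `agent`, `Dm`, `m`, `r`, `dose_unit`, `is_combination`.
#' @export
dhodh_reference_fits <- function() {
  tibble(
    agent = c("allium_sativum", "silymarin", "silibinin", "brequinar",
              "allium_sativum + brequinar", "silymarin + brequinar",
              "silibinin + brequinar"),
    Dm = c(202.972, 133.538, 122.127, 9.76713, 141.25, 135.453, 127.135),
    m = c(1.26701, 1.56510, 1.00184, 1.33376, 1.107, 1.027, 2.2),
    r = c(0.99998, 1.00000, 0.99999, 0.99999, 0.99889, 0.99999, 0.98999),
    dose_unit = c("ug/ml", "ug/ml", "nM", "nM", "ug/ml", "ug/ml", "nM"),
    is_combination = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Benchmark combination CI/DRI tables
#'
#' Published per-effect-level combination results for the three binary
#' combinations with brequinar: measured combined-drug inhibition
#' (`fa_percent`), printed combination index, component doses and both
#' dose-reduction indices, with the printed interaction call. `dose_a`
#' and `dri_a` refer to the botanical partner, `dose_b`/`dri_b` to
#' brequinar.
#'
#' @return A tibble with 15 rows (5 effect levels x 3 combinations).
#' @export
dhodh_combination_dri <- function() {
  tribble_rows <- list(
    list("allium_sativum + brequinar", 11, 1.84, 39.32, 2.05, 1.09, 1.09, "antagonism"),
    list("allium_sativum + brequinar", 39, 1.46, 142.08, 6.96, 1.38, 1.35, "antagonism"),
    list("allium_sativum + brequinar", 72, 0.95, 431.44, 19.99, 2.14, 2.05, "synergism"),
    list("allium_sativum + brequinar", 78, 1.46, 545.62, 24.99, 1.38, 1.36, "antagonism"),
    list("allium_sativum + brequinar", 98, 0.47, 5062.94, 207.41, 4.38, 4.08, "synergism"),
    list("silibinin + brequinar", 6, 3.49, 7.23, 1.17, 0.53, 0.62, "antagonism"),
    list("silibinin + brequinar", 44, 1.14, 97.72, 8.26, 1.85, 1.61, "antagonism"),
    list("silibinin + brequinar", 61, 1.34, 191.74, 13.71, 1.57, 1.40, "antagonism"),
    list("silibinin + brequinar", 78, 1.40, 426.52, 24.99, 1.50, 1.36, "antagonism"),
    list("silibinin + brequinar", 99, 0.16, 21481.50, 474.52, 19.63, 9.33, "synergism"),
    list("silymarin + brequinar", 17, 1.33, 47.76, 2.92, 1.46, 1.55, "antagonism"),
    list("silymarin + brequinar", 33, 1.79, 85.75, 5.81, 1.10, 1.13, "antagonism"),
    list("silymarin + brequinar", 72, 1.03, 245.88, 19.99, 1.84, 2.05, "additive"),
    list("silymarin + brequinar", 83, 1.14, 373.37, 32.64, 1.63, 1.77, "antagonism"),
    list("silymarin + brequinar", 98, 0.55, 1805.11, 207.41, 3.32, 4.08, "synergism")
  )
  purrr::map(tribble_rows, ~ tibble(
    combination = .x[[1]], fa_percent = .x[[2]], ci_printed = .x[[3]],
    dose_a = .x[[4]], dose_b = .x[[5]], dri_a = .x[[6]], dri_b = .x[[7]],
    label_printed = .x[[8]])) |> list_rbind()
}

#' Write the benchmark tables as a CSV fixture bundle
#'
#' Serializes [dhodh_dose_effect()] (in the [read_dose_effect_csv()]
#' schema), [dhodh_reference_fits()] and [dhodh_combination_dri()] into a
#' directory, so the whole benchmark is available as plain-text files for
#' pipelines and round-trip tests.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths
#'   (`dose_effect`, `reference_fits`, `combination_dri`).
#' @export
write_benchmark_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dose_effect = file.path(dir, "dhodh_dose_effect.csv"),
    reference_fits = file.path(dir, "dhodh_reference_fits.csv"),
    combination_dri = file.path(dir, "dhodh_combination_dri.csv"))
  readr::write_csv(dhodh_dose_effect(), paths[["dose_effect"]])
  readr::write_csv(dhodh_reference_fits(), paths[["reference_fits"]])
  readr::write_csv(dhodh_combination_dri(), paths[["combination_dri"]])
  invisible(paths)
}
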