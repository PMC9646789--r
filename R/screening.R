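#' Select active docking hits
#'
#' Filters a per-compound docking-score table to the "active hits": the
#' compounds whose score is at or below a cutoff (Glide convention — more
#' negative means better predicted binding). The result is deterministic:
#' hits are ordered by score ascending, ties by compound id.
#'
#' @param scores A tibble with columns `plant`, `compound_id`,
#'   `xp_gscore` (kcal/mol).
#' @param hit_threshold Score cutoff; a compound is a hit when
#'   `xp_gscore <= hit_threshold`. There is no universal default — the
#'   cutoff is assay- and target-specific (e.g. -10 kcal/mol is a common
#'   stringent choice) — so it must be supplied.
#' @return The hit subset, same columns, ordered (score, id).
#' @export
select_hits <- function(scores, hit_threshold) {
  if (!is.numeric(hit_threshold) || length(hit_threshold) != 1L ||
      is.na(hit_threshold)) {
    abort("`hit_threshold` must be a single numeric score cutoff.",
          class = "chousyn_validation_error")
  }
  if (any(!is.finite(scores$xp_gscore))) {
    abort("Docking scores must be finite.",
          class = "chousyn_validation_error")
  }
  scores |>
    filter(.data$xp_gscore <= hit_threshold) |>
    arrange(.data$xp_gscore, .data$compound_id)
}

#' Per-plant virtual-screening activity score
#'
#' Aggregates per-compound docking scores into one activity score per
#' plant. Because the number of catalogued constituents differs between
#' plants, the raw sum of hit scores is penalized by the hit fraction:
#' `score = (sum of hit docking scores) * (n_hits / total_in_database)`.
#' With every score negative, a more negative plant score means more (and
#' better-scoring) hits relative to the plant's catalogue size. A plant
#' with no hits scores 0.
#'
#' @param scores Per-compound score tibble (`plant`, `compound_id`,
#'   `xp_gscore`), e.g. from [read_docking_csv()].
#' @param totals Tibble `plant`, `total_in_database` (> 0).
#' @param hit_threshold Cutoff passed to [select_hits()].
#' @return A tibble with one row per plant in `totals`: `plant`,
#'   `n_hits`, `sum_hit_scores`, `total_in_database`, `score`.
#' @examples
#' scores <- tibble::tibble(plant = "x", compound_id = as.character(1:3),
#'                          xp_gscore = c(-10, -8, -6))
#' totals <- tibble::tibble(plant = "x", total_in_database = 10L)
#' plant_score(scores, totals, hit_threshold = -5)$score # -7.2
#' @export
plant_score <- function(scores, totals, hit_threshold) {
  if (any(totals$total_in_database <= 0)) {
    abort("`total_in_database` must be > 0 for every plant.",
          class = "chousyn_domain_error")
  }
  hits <- select_hits(scores, hit_threshold)
  per_plant <- hits |>
    group_by(.data$plant) |>
    summarise(n_hits = n(), sum_hit_scores = sum(.data$xp_gscore),
              .groups = "drop")
  totals |>
    left_join(per_plant, by = "plant") |>
    mutate(
      n_hits = ifelse(is.na(.data$n_hits), 0L, .data$n_hits),
      sum_hit_scores = ifelse(is.na(.data$sum_hit_scores), 0,
                              .data$sum_hit_scores),
      score = .data$sum_hit_scores * .data$n_hits / .data$total_in_database
    ) |>
    select("plant", "n_hits", "sum_hit_scores", "total_in_database", "score")
}

#' Rank plants by activity score
#'
#' Orders plant scores most-active first: ascending score (most negative
#' = strongest aggregate predicted activity), ties broken alphabetically
#' by plant label.
#'
#' @param scores A tibble from [plant_score()] (needs `plant` and
#'   `score`).
#' @return The tibble ordered by rank with a `rank` column prepended.
#' @export
rank_plants <- function(scores) {
  if (nrow(scores) == 0L) {
    abort("Cannot rank an empty score table.",
          class = "chousyn_validation_error")
  }
  scores |>
    arrange(.data$score, .data$plant) |>
    mutate(rank = row_number(), .before = 1)
}
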