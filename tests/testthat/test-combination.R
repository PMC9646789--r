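fit_a <- medfit("A", Dm = 10, m = 1, dose_unit = "nM")
fit_b <- medfit("B", Dm = 100, m = 2, dose_unit = "ug/ml")

test_that("combination index recovers the Loewe additivity anchors", {
  dx_a <- dose_for_effect(fit_a, 0.6)
  dx_b <- dose_for_effect(fit_b, 0.6)
  expect_equal(combination_index(dx_a, 0, fit_a, fit_b, 0.6), 1,
               tolerance = 1e-12)
  expect_equal(combination_index(dx_a / 2, dx_b / 2, fit_a, fit_b, 0.6), 1,
               tolerance = 1e-12)
  # the benchmark 98%-level dose reductions
  dx_a98 <- dose_for_effect(fit_a, 0.98)
  dx_b98 <- dose_for_effect(fit_b, 0.98)
  ci <- combination_index(dx_a98 / 4.38, dx_b98 / 4.08, fit_a, fit_b, 0.98)
  expect_equal(ci, 0.473, tolerance = 1e-3)
  expect_equal(round(ci, 2), 0.47)

  expect_error(combination_index(0, 0, fit_a, fit_b, 0.5),
               class = "chousyn_domain_error")
  expect_error(combination_index(1, 1, fit_a, fit_b, 1.2),
               class = "chousyn_domain_error")
})

test_that("dose-reduction index is the fold reduction at equal effect", {
  dx <- dose_for_effect(fit_a, 0.9)
  expect_equal(dose_reduction_index(fit_a, dx, 0.9), 1, tolerance = 1e-12)
  expect_equal(dose_reduction_index(fit_a, dx / 2, 0.9), 2, tolerance = 1e-12)
  breq <- medfit("brequinar", Dm = 9.76713, m = 1.33376, dose_unit = "nM")
  expect_equal(dose_reduction_index(breq, 25.37, 0.9), 2, tolerance = 0.01)
  expect_error(dose_reduction_index(fit_a, 0, 0.5),
               class = "chousyn_domain_error")
})

test_that("ci_from_dri is the exact algebraic twin of combination_index", {
  expect_equal(ci_from_dri(2, 2), 1)
  expect_equal(round(ci_from_dri(19.63, 9.33), 2), 0.16)
  expect_equal(round(ci_from_dri(3.32, 4.08), 2), 0.55)
  expect_error(ci_from_dri(-1, 2), class = "chousyn_domain_error")

  set.seed(42)
  for (i in 1:50) {
    fa <- runif(1, 0.05, 0.95)
    da <- runif(1, 0.1, 50); db <- runif(1, 0.1, 50)
    dri_a <- dose_reduction_index(fit_a, da, fa)
    dri_b <- dose_reduction_index(fit_b, db, fa)
    expect_equal(ci_from_dri(dri_a, dri_b),
                 combination_index(da, db, fit_a, fit_b, fa),
                 tolerance = 1e-12)
  }
})

test_that("interaction labels respect the additive band", {
  expect_equal(classify_interaction(0.47), "synergism")
  expect_equal(classify_interaction(1.03, 0.05), "additive")
  expect_equal(classify_interaction(1.14, 0.05), "antagonism")
  expect_equal(classify_interaction(c(0.8, 1.0, 1.2)),
               c("synergism", "additive", "antagonism"))
  # band edges are inclusive
  expect_equal(classify_interaction(c(0.95, 1.05), 0.05),
               c("additive", "additive"))
  expect_error(classify_interaction(0), class = "chousyn_domain_error")
})

test_that("isobologram side-of-line always agrees with the CI label", {
  iso <- isobologram_point(0.5 * dose_for_effect(fit_a, 0.5),
                           0.5 * dose_for_effect(fit_b, 0.5),
                           fit_a, fit_b, 0.5)
  expect_equal(iso$side, "on")
  expect_equal(iso$x + iso$y, 1, tolerance = 1e-12)
  iso <- isobologram_point(dose_for_effect(fit_a, 0.5) / 4.38,
                           dose_for_effect(fit_b, 0.5) / 4.08,
                           fit_a, fit_b, 0.5)
  expect_equal(iso$side, "below")
  iso <- isobologram_point(0.9 * dose_for_effect(fit_a, 0.5),
                           0.9 * dose_for_effect(fit_b, 0.5),
                           fit_a, fit_b, 0.5)
  expect_equal(iso$side, "above")

  set.seed(7)
  side_to_label <- c(below = "synergism", on = "additive",
                     above = "antagonism")
  for (i in 1:50) {
    fa <- runif(1, 0.05, 0.95)
    da <- runif(1, 0.01, 3) * dose_for_effect(fit_a, fa)
    db <- runif(1, 0.01, 3) * dose_for_effect(fit_b, fa)
    ci <- combination_index(da, db, fit_a, fit_b, fa)
    iso <- isobologram_point(da, db, fit_a, fit_b, fa)
    expect_equal(unname(side_to_label[iso$side]), classify_interaction(ci))
  }
})

test_that("CI is invariant to per-agent unit rescaling", {
  set.seed(11)
  for (i in 1:20) {
    fa <- runif(1, 0.1, 0.9)
    da <- runif(1, 1, 20); db <- runif(1, 1, 200)
    ci0 <- combination_index(da, db, fit_a, fit_b, fa)
    ka <- runif(1, 0.01, 100); kb <- runif(1, 0.01, 100)
    fa_scaled <- medfit("A", Dm = fit_a$Dm * ka, m = fit_a$m)
    fb_scaled <- medfit("B", Dm = fit_b$Dm * kb, m = fit_b$m)
    ci1 <- combination_index(da * ka, db * kb, fa_scaled, fb_scaled, fa)
    expect_equal(ci1, ci0, tolerance = 1e-10)
  }
})

test_that("the Loewe solver matches a fine grid search and its anchors", {
  # identical agents reduce to the single-agent law
  expect_equal(solve_loewe_mixture(fit_a, fit_a, c(0.5, 0.5), 10), 0.5,
               tolerance = 1e-8)
  expect_equal(solve_loewe_mixture(fit_a, fit_a, c(0.5, 0.5), 90), 0.9,
               tolerance = 1e-8)

  fa_hat <- solve_loewe_mixture(fit_a, fit_b, c(0.5, 0.5), 60)
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1e6)
  lhs <- 0.5 * 60 / dose_for_effect(fit_a, grid) +
    0.5 * 60 / dose_for_effect(fit_b, grid)
  fa_grid <- grid[which.min(abs(lhs - 1))]
  expect_equal(fa_hat, fa_grid, tolerance = 1e-6)

  expect_error(solve_loewe_mixture(fit_a, fit_b, c(0.5, 0.5), -1),
               class = "chousyn_domain_error")
  expect_error(solve_loewe_mixture(fit_a, fit_b, c(0.7, 0.7), 10),
               class = "chousyn_domain_error")
})

test_that("fa-CI profiles flag self-combinations as additive everywhere", {
  grid <- seq(0.1, 0.9, by = 0.1)
  prof <- fa_ci_profile(fit_a, c(1, 0), fit_a, fit_b, fa_grid = grid)
  expect_equal(prof$ci, rep(1, length(grid)), tolerance = 1e-12)
  expect_true(all(prof$label == "additive"))
  expect_error(fa_ci_profile(fit_a, c(1, 0), fit_a, fit_b,
                             fa_grid = numeric()),
               class = "chousyn_domain_error")
})

test_that("equal-slope Loewe mixtures profile at CI = 1 exactly", {
  # with equal m the Loewe mixture is itself a median-effect curve:
  # Dm_mix = 1 / (p/Dm_a + q/Dm_b), same m
  a <- medfit("A", Dm = 20, m = 1.4)
  b <- medfit("B", Dm = 200, m = 1.4)
  p <- 0.3; q <- 0.7
  dm_mix <- 1 / (p / 20 + q / 200)
  combo <- medfit("A + B", Dm = dm_mix, m = 1.4)
  prof <- fa_ci_profile(combo, c(p, q), a, b,
                        fa_grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(prof$ci, rep(1, nrow(prof)), tolerance = 1e-6)
})

test_that("a combo fit below the additive isobole scores synergistic", {
  a <- medfit("A", Dm = 20, m = 1.4)
  b <- medfit("B", Dm = 200, m = 1.4)
  dm_add <- 1 / (0.5 / 20 + 0.5 / 200)
  combo <- medfit("A + B", Dm = dm_add / 3, m = 1.4)
  prof <- fa_ci_profile(combo, c(0.5, 0.5), a, b, fa_grid = c(0.5, 0.9))
  expect_true(all(prof$ci < 1))
  expect_true(all(prof$label == "synergism"))
})

test_that("assess_combination bundles points, isobologram and labels", {
  a <- medfit("A", Dm = 20, m = 1.4, dose_unit = "nM")
  b <- medfit("B", Dm = 200, m = 1.4, dose_unit = "nM")
  dm_mix <- 1 / (0.5 / 20 + 0.5 / 200)
  combo <- medfit("A + B", Dm = dm_mix, m = 1.4, dose_unit = "mixture")
  cb <- assess_combination(a, b, combo, ratio_fractions = c(0.5, 0.5))
  expect_s3_class(cb, "combo_assessment")
  expect_equal(nrow(cb$points), 5)
  expect_true(all(cb$points$label == "additive"))
  expect_true(all(cb$isobologram$side == "on"))
  # label consistency invariant between the two views
  side_to_label <- c(below = "synergism", on = "additive",
                     above = "antagonism")
  expect_equal(unname(side_to_label[cb$isobologram$side]), cb$points$label)
  gl <- glance(cb)
  expect_equal(gl$n_additive, 5)
  expect_equal(nrow(tidy(cb)), 5)
  # default ratio is Dm-proportional
  cb2 <- assess_combination(a, b, combo)
  expect_equal(cb2$ratio_fractions, c(20, 200) / 220)
})
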