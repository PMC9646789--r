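test_that("two exact points solve the median-effect line in closed form", {
  pts <- tibble::tibble(agent = "a", dose = c(10, 30), dose_unit = "nM",
                        fa = c(0.5, 0.75))
  fit <- fit_median_effect(pts)
  expect_equal(fit$m, 1, tolerance = 1e-12)
  expect_equal(fit$Dm, 10, tolerance = 1e-10)
})

test_that("noiseless median-effect data refit exactly", {
  doses <- c(5, 12, 30, 50, 75, 120, 400)
  pts <- exact_points(Dm = 50, m = 2, doses = doses)
  fit <- fit_median_effect(pts)
  expect_equal(fit$Dm, 50, tolerance = 1e-9)
  expect_equal(fit$m, 2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 7)
})

test_that("fit validation: too few points, degenerate design, mixed units", {
  pts <- exact_points(50, 2, doses = c(50))
  expect_error(fit_median_effect(pts),
               class = "chousyn_insufficient_data_error")
  same <- tibble::tibble(agent = "a", dose = c(10, 10), dose_unit = "nM",
                         fa = c(0.4, 0.6))
  expect_error(fit_median_effect(same),
               class = "chousyn_degenerate_design_error")
  mixed <- tibble::tibble(agent = "a", dose = c(10, 30),
                          dose_unit = c("nM", "ug/ml"), fa = c(0.4, 0.6))
  expect_error(fit_median_effect(mixed), class = "chousyn_unit_error")
  # points outside the clip bounds never enter the fit
  clipped <- tibble::tibble(agent = "a", dose = c(10, 30, 60),
                            dose_unit = "nM", fa = c(0.5, 0.75, 0.999))
  fit <- fit_median_effect(clipped)
  expect_equal(fit$n_points, 2)
})

test_that("effect_at_dose and dose_for_effect are mutual inverses", {
  fit <- medfit("a", Dm = 9.76713, m = 1.33376, dose_unit = "nM")
  expect_equal(effect_at_dose(fit, 9.76713), 0.5, tolerance = 1e-12)
  fit1 <- medfit("b", Dm = 10, m = 1)
  expect_equal(effect_at_dose(fit1, 20), 2 / 3, tolerance = 1e-12)
  expect_equal(dose_for_effect(fit1, 0.9), 90, tolerance = 1e-10)
  expect_equal(dose_for_effect(fit1, 0.5), 10, tolerance = 1e-12)

  fa <- seq(0.01, 0.99, by = 0.01)
  back <- effect_at_dose(fit, dose_for_effect(fit, fa))
  expect_equal(back, fa, tolerance = 1e-10)
  # monotone in dose
  d <- dose_for_effect(fit, fa)
  expect_true(all(diff(d) > 0))

  expect_error(effect_at_dose(fit, -1), class = "chousyn_domain_error")
  expect_error(dose_for_effect(fit, 1), class = "chousyn_domain_error")
})

test_that("the fit is scale-equivariant in dose", {
  doses <- c(4, 11, 19, 37, 102)
  pts <- exact_points(Dm = 20, m = 1.3, doses = doses)
  fit1 <- fit_median_effect(pts)
  for (c_scale in c(0.5, 2, 17.3)) {
    pts2 <- dplyr::mutate(pts, dose = dose * c_scale)
    fit2 <- fit_median_effect(pts2)
    expect_equal(fit2$m, fit1$m, tolerance = 1e-10)
    expect_equal(fit2$r, fit1$r, tolerance = 1e-12)
    expect_equal(fit2$Dm, fit1$Dm * c_scale, tolerance = 1e-9)
  }
})

test_that("median-effect plot coordinates are the log-transformed pairs", {
  pts <- tibble::tibble(agent = "a", dose = c(10, 50), dose_unit = "nM",
                        fa = c(0.5, 0.9))
  xy <- median_effect_points(pts)
  expect_equal(xy$y[1], 0, tolerance = 1e-12)
  expect_equal(xy$y[2], log10(9), tolerance = 1e-12)
  expect_equal(xy$x, log10(c(10, 50)))

  # benchmark silibinin pairs are collinear
  sil <- dplyr::filter(dhodh_dose_effect(), agent == "silibinin")
  xy <- median_effect_points(sil)
  expect_equal(nrow(xy), 5)
  expect_gt(stats::cor(xy$x, xy$y), 0.999)
})

test_that("constrained Hill fit recovers noiseless parameters", {
  doses <- c(20, 60, 121.2, 250, 700)
  ratio <- (doses / 121.2)^1
  pts <- tibble::tibble(agent = "a", dose = doses, dose_unit = "nM",
                        fa = ratio / (1 + ratio))
  h <- fit_hill(pts)
  expect_true(h$converged)
  expect_equal(h$ic50, 121.2, tolerance = 1e-6)
  expect_equal(h$hill_slope, 1, tolerance = 1e-6)
  expect_equal(h$bottom, 0)
  expect_equal(h$top, 100)
})

test_that("constrained Hill and median-effect fits coincide on exact data", {
  pts <- exact_points(Dm = 122.127, m = 1.00184,
                      doses = c(30, 80, 122, 300, 900))
  me <- fit_median_effect(pts)
  h <- fit_hill(pts)
  expect_equal(h$ic50, me$Dm, tolerance = 1e-6)
  expect_equal(h$hill_slope, me$m, tolerance = 1e-6)
})

test_that("under-determined Hill fits are refused", {
  pts <- exact_points(50, 1, doses = c(20, 80))
  expect_error(fit_hill(pts, fix_bottom = NA, fix_top = NA),
               class = "chousyn_insufficient_data_error")
  expect_error(fit_hill(pts), class = "chousyn_insufficient_data_error")
})

test_that("tidy and glance methods return one-row-per-term tibbles", {
  pts <- exact_points(50, 2, doses = c(10, 30, 50, 100, 300))
  fit <- fit_median_effect(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("Dm", "m"))
  expect_equal(td$estimate, c(50, 2), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 5)
  h <- fit_hill(pts)
  expect_equal(nrow(tidy(h)), 4)
  expect_true(glance(h)$converged)
})
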