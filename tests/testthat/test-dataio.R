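test_that("trace CSV is grouped into wells with validated schema", {
  lines <- c("time_min,a600,agent,dose,dose_unit,replicate,is_control")
  for (w in 1:2) {
    for (t in 0:5) {
      lines <- c(lines, sprintf("%d,%.4f,drugA,%d,nM,1,%s",
                                t, 1 - 0.01 * t * w, (w - 1) * 10,
                                ifelse(w == 1, "TRUE", "FALSE")))
    }
  }
  tr <- read_trace_csv(write_csv_text(lines))
  wells <- dplyr::distinct(tr, agent, dose, replicate)
  expect_equal(nrow(tr), 12)
  expect_equal(nrow(wells), 2)
  expect_true(all(dplyr::count(tr, agent, dose, replicate)$n == 6))
  # times strictly increasing within each well
  ok <- tr |>
    dplyr::group_by(agent, dose, replicate) |>
    dplyr::summarise(inc = all(diff(time_min) > 0), .groups = "drop")
  expect_true(all(ok$inc))
})

test_that("trace CSV validation names file, row and rule", {
  base <- c("time_min,a600,agent,dose,dose_unit,replicate,is_control",
            "0,1.0,drugA,10,nM,1,FALSE",
            "1,0.99,drugA,10,nM,1,FALSE",
            "2,0.98,drugA,10,nM,1,FALSE")
  # missing column
  p <- write_csv_text(c("time_min,a600,agent,dose,replicate,is_control",
                        "0,1.0,drugA,10,1,FALSE"))
  expect_error(read_trace_csv(p), "dose_unit", class = "chousyn_schema_error")
  # non-numeric absorbance, with row number
  p <- write_csv_text(c(base, "3,oops,drugA,10,nM,1,FALSE"))
  expect_error(read_trace_csv(p), "row 5.*a600", class = "chousyn_parse_error")
  # duplicate record
  p <- write_csv_text(c(base, "2,0.98,drugA,10,nM,1,FALSE"))
  expect_error(read_trace_csv(p), "duplicate",
               class = "chousyn_duplicate_error")
  # mixed units within one agent
  p <- write_csv_text(c(base, "0,1.0,drugA,5,ug/ml,2,FALSE",
                        "1,0.99,drugA,5,ug/ml,2,FALSE",
                        "2,0.98,drugA,5,ug/ml,2,FALSE"))
  expect_error(read_trace_csv(p), "mixed dose units",
               class = "chousyn_unit_error")
  # control wells must sit at dose zero
  p <- write_csv_text(c(base[1], "0,1.0,drugA,10,nM,1,TRUE",
                        "1,0.99,drugA,10,nM,1,TRUE",
                        "2,0.98,drugA,10,nM,1,TRUE"))
  expect_error(read_trace_csv(p), "dose = 0",
               class = "chousyn_validation_error")
})

test_that("header-only trace file gives an empty collection with a warning", {
  p <- write_csv_text("time_min,a600,agent,dose,dose_unit,replicate,is_control")
  expect_warning(tr <- read_trace_csv(p), "No data rows")
  expect_equal(nrow(tr), 0)
  expect_named(tr, c("time_min", "a600", "agent", "dose", "dose_unit",
                     "replicate", "is_control"))
})

test_that("dose-effect CSV accepts the benchmark rows and flags boundaries", {
  de <- dhodh_dose_effect()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(de[de$agent == "brequinar", ], path)
  pts <- read_dose_effect_csv(path)
  expect_equal(nrow(pts), 5)
  expect_true(all(pts$fittable))
  expect_equal(pts$dose, c(3.78, 10.28, 19.54, 36.82, 101.74))

  # fa = 1 is valid input but unusable by the log transform
  p <- write_csv_text(c("agent,dose,dose_unit,fa", "a,10,nM,1.0"))
  expect_message(pts <- read_dose_effect_csv(p), "non-fittable")
  expect_false(pts$fittable[1])

  p <- write_csv_text(c("agent,dose,dose_unit,fa", "a,0,nM,0.5"))
  expect_error(read_dose_effect_csv(p), "dose must be > 0",
               class = "chousyn_validation_error")
  p <- write_csv_text(c("agent,dose,dose_unit,fa", "a,10,nM,1.2"))
  expect_error(read_dose_effect_csv(p), "fa must lie",
               class = "chousyn_validation_error")
})

test_that("reports round-trip at full precision and are deterministic", {
  pts <- exact_points(Dm = 37.5, m = 1.7, doses = c(5, 15, 40, 90, 250))
  fit <- fit_median_effect(pts)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.json"); p2 <- file.path(d, "r2.json")
  write_report(list(fits = list(fit)), p1)
  write_report(list(fits = list(fit)), p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_report(p1)
  expect_identical(back$fits[[1]]$Dm, fit$Dm)
  expect_identical(back$fits[[1]]$m, fit$m)
  expect_equal(back$fits[[1]]$r, fit$r)
  expect_equal(length(back$combinations), 0)
  expect_equal(back$provenance$seed, 1)

  expect_error(write_report(list(fits = list()), p1),
               "at least one", class = "chousyn_validation_error")
})

test_that("CI/DRI table export keeps the canonical column set", {
  a <- medfit("A", 10, 1, dose_unit = "nM")
  b <- medfit("B", 100, 2, dose_unit = "nM")
  combo <- medfit("A + B", 50, 1.5, dose_unit = "mixture")
  pts <- fa_ci_profile(combo, c(0.3, 0.7), a, b, fa_grid = c(0.25, 0.5, 0.75))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ci_table_csv(pts, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("fa", "dose_a", "dose_b", "dx_a", "dx_b", "ci",
                       "dri_a", "dri_b", "label"))
  expect_equal(back$ci, pts$ci)
  expect_error(write_ci_table_csv(pts[, 1:3], path),
               class = "chousyn_schema_error")
})

test_that("study configuration enforces its invariants", {
  cfg <- study_config()
  expect_s3_class(cfg, "chousyn_config")
  expect_error(study_config(clip_bounds = c(0.6, 0.9)),
               class = "chousyn_config_error")
  expect_error(study_config(additive_band = -0.1),
               class = "chousyn_config_error")
  expect_error(study_config(log_base = 1),
               class = "chousyn_config_error")

  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"additive_band": 0.1, "seed": 42}', path)
  cfg <- read_config(path)
  expect_equal(cfg$additive_band, 0.1)
  expect_equal(cfg$seed, 42L)
  writeLines('{"bogus_field": 1}', path)
  expect_error(read_config(path), "bogus_field",
               class = "chousyn_config_error")
})
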