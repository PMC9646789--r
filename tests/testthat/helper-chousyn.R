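# shared builders for the test suite; everything is generated in code

# exact straight-line trace tibble for one well
line_trace <- function(slope, intercept = 1, times = 0:5) {
  tibble::tibble(time_min = as.numeric(times),
                 a600 = intercept + slope * times)
}

# dose-effect points generated exactly from the median-effect law
exact_points <- function(Dm, m, doses, agent = "synthA", unit = "nM") {
  ratio <- (doses / Dm)^m
  tibble::tibble(agent = agent, dose = doses, dose_unit = unit,
                 fa = ratio / (1 + ratio))
}

# write a CSV of rows (list of character vectors) under a temp path
write_csv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force best-window oracle for the "auto" velocity policy
brute_best_window <- function(t, y) {
  n <- length(t)
  min_len <- max(3L, ceiling(n / 2))
  best <- NULL
  for (len in min_len:n) {
    for (start in 1:(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      fit <- stats::lm(y[idx] ~ t[idx])
      tss <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (tss <= .Machine$double.eps * max(1, sum(y[idx]^2))) 1 else {
        max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
      }
      if (is.null(best) || r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
           (start < best$start ||
            (start == best$start && len > best$len)))) {
        best <- list(start = start, len = len, r2 = r2,
                     slope = unname(stats::coef(fit)[2]))
      }
    }
  }
  best
}
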