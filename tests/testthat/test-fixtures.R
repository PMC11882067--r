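test_that("synthetic KM curves are reproducible, monotone and anchored", {
  spec <- km_curve_spec(seed = 42L, n_subjects = 300)
  c1 <- generate_km_curve(spec)
  c2 <- generate_km_curve(spec)
  expect_identical(c1$time, c2$time)
  expect_identical(c1$survival, c2$survival)
  expect_equal(c1$survival[1], 1)
  expect_true(all(diff(c1$survival) <= 1e-12))
  expect_true(all(c1$survival >= 0 & c1$survival <= 1))

  tuned <- anchor_tune(c1, 24, 0.5)
  s24 <- exp(stats::approx(tuned$time, log(pmax(tuned$survival, 1e-12)),
                           xout = 24, rule = 2)$y)
  expect_equal(s24, 0.5, tolerance = 1e-6)
})

test_that("packaged curves reproduce the configured anchors within 0.01", {
  cfg <- base_case_config()
  curves <- packaged_curves(cfg)
  interp <- function(curve, t) {
    exp(stats::approx(curve$time, log(pmax(curve$survival, 1e-12)),
                      xout = t, rule = 2)$y)
  }
  for (st in names(curves$os)) {
    expect_lt(abs(interp(curves$os[[st]], 60) -
                    cfg$survival_inputs$os_5y_by_stage[[st]]), 0.01)
    expect_lt(abs(interp(curves$dfs[[st]], 12) -
                    cfg$survival_inputs$dfs_1y_by_stage[[st]]), 0.01)
  }
})

test_that("curve files round-trip through the delimited format", {
  curve <- generate_km_curve(km_curve_spec(seed = 7L, n_subjects = 200))
  path <- tempfile(fileext = ".tsv")
  write_curve(curve, path)
  back <- read_curve(path, endpoint = curve$endpoint, stage = curve$stage)
  expect_equal(back$time, curve$time, tolerance = 1e-5)
  expect_equal(back$survival, curve$survival, tolerance = 1e-5)
  expect_equal(back$at_risk$n_risk, curve$at_risk$n_risk)
})

test_that("life table is a valid mortality schedule", {
  lt <- generate_life_table()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$qx[nrow(lt)], 1)
  expect_true(all(diff(lt$qx) >= 0))
  le58 <- life_expectancy(lt, 58)
  le70 <- life_expectancy(lt, 70)
  expect_gt(le58, le70)
  expect_gt(le58, 18)
  expect_lt(le58, 30)
  # scenario multiplier shortens life
  lt2 <- generate_life_table(multiplier = 2)
  expect_lt(life_expectancy(lt2, 58), le58)
})

test_that("packaged text fixtures respect the size budget", {
  extdata <- system.file("extdata", package = "lcscreen")
  files <- list.files(extdata, full.names = TRUE, recursive = TRUE)
  expect_gt(length(files), 0)
  sizes <- file.size(files)
  expect_true(all(sizes <= 64 * 1024))
  expect_lte(sum(sizes), 256 * 1024)
})
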