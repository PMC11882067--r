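make_curve <- function(seed = 11L, n = 500, rate = log(2) / 24) {
  generate_km_curve(km_curve_spec(family = "exponential",
                                  params = list(rate = rate),
                                  n_subjects = n, seed = seed))
}

test_that("reconstruct_ipd inverts a digitised curve", {
  curve <- make_curve()
  ipd <- reconstruct_ipd(curve)
  expect_s3_class(ipd, "reconstructed_ipd")
  expect_true(all(ipd$time >= 0))
  expect_true(all(ipd$status %in% c(0L, 1L)))
  expect_equal(length(ipd$time), length(ipd$status))

  bad <- curve
  bad$survival <- rev(bad$survival)
  expect_error(reconstruct_ipd(bad), "non-increasing")
})

test_that("reconstruction round-trip deviates at most 0.02 from the curve", {
  curve <- make_curve(seed = 3L)
  ipd <- reconstruct_ipd(curve)
  km <- km_from_ipd(ipd, curve$time)
  expect_lte(max(abs(km - curve$survival)), 0.02)
})

test_that("parametric fits recover generating parameters within 10% at n=500", {
  rate <- log(2) / 24
  ipd <- reconstruct_ipd(make_curve(seed = 5L, n = 500, rate = rate))
  fit <- fit_parametric(ipd, "exponential")
  expect_lt(abs(fit$params[["rate"]] - rate) / rate, 0.10)
  expect_equal(survival_at(fit, 0), 1)
  expect_true(all(diff(survival_at(fit, c(0, 12, 24, 48))) < 0))
})

test_that("family selection honours AIC and the pinning override", {
  ipd <- reconstruct_ipd(make_curve(seed = 9L))
  fits <- fit_families(ipd, families = c("exponential", "weibull", "lognormal"))
  expect_gte(length(fits), 2)
  best <- select_fit(fits)
  expect_equal(best$aic, min(vapply(fits, `[[`, 0, "aic")))
  pinned <- select_fit(fits, pin = "exponential")
  expect_equal(pinned$family, "exponential")
  expect_error(select_fit(fits, pin = "gompertz"), "not fitted")
})

test_that("cycle probabilities recompose the fitted survival to 1e-12", {
  ipd <- reconstruct_ipd(make_curve(seed = 13L))
  fit <- fit_parametric(ipd, "weibull")
  p <- cycle_event_probs(fit, 3, 80)
  s_recomposed <- cumprod(1 - p)
  s_direct <- survival_at(fit, seq_len(80) * 3)
  expect_equal(s_recomposed, s_direct, tolerance = 1e-12)
})

test_that("annual probabilities convert consistently to the cycle scale", {
  p_annual <- 0.08
  p_cycle <- annual_to_cycle(p_annual, 3)
  expect_equal(1 - (1 - p_cycle)^4, p_annual, tolerance = 1e-12)
  expect_equal(annual_to_cycle(0, 3), 0)
})

test_that("the background-mortality floor binds where disease risk is lower", {
  lt <- generate_life_table()
  ages <- seq(58, 90, by = 0.25)
  disease <- rep(0.0005, length(ages))
  floored <- apply_mortality_floor(disease, lt, ages, 3)
  expect_true(all(floored >= disease))
  expect_gt(floored[length(floored)], disease[length(floored)])
  expect_error(apply_mortality_floor(0.1, lt, 200, 3), "range")
})

test_that("the fitted survival set matches the configured anchors", {
  for (st in names(PREP$fits$os)) {
    ac <- PREP$fits$os[[st]]$anchor_check
    expect_lt(abs(ac$fitted - ac$target), 0.01)
    ac <- PREP$fits$dfs[[st]]$anchor_check
    expect_lt(abs(ac$fitted - ac$target), 0.01)
    expect_equal(PREP$fits$os[[st]]$family, "exponential")  # base-case pin
  }
})
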