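test_that("Dirichlet draws stay on the simplex", {
  probs <- c(0.0959, 0.0959, 0.2814, 0.5268)
  d <- lcscreen:::.draw_dirichlet(500, probs, 100)
  expect_equal(rowSums(d), rep(1, 500), tolerance = 1e-12)
  expect_true(all(d >= 0))
  expect_equal(colMeans(d), probs, tolerance = 0.02)
  # higher concentration, lower spread
  d_tight <- lcscreen:::.draw_dirichlet(500, probs, 10000)
  expect_lt(sd(d_tight[, 4]), sd(d[, 4]))
})

test_that("Beta and Gamma draws are moment-matched", {
  set.seed(1)
  b <- lcscreen:::.draw_beta(20000, 0.66, 0.066)
  expect_equal(mean(b), 0.66, tolerance = 0.01)
  expect_equal(sd(b), 0.066, tolerance = 0.01)
  expect_true(all(b > 0 & b < 1))
  g <- lcscreen:::.draw_gamma(20000, 8959, 895.9)
  expect_equal(mean(g), 8959, tolerance = 0.01 * 8959)
  expect_equal(sd(g), 895.9, tolerance = 0.05 * 895.9)
  expect_true(all(g > 0))
})

test_that("PSA is seed-reproducible and respects config constraints", {
  p1 <- sample_psa(CFG, n_draws = 20, seed = 99L, prepared = PREP)
  p2 <- sample_psa(CFG, n_draws = 20, seed = 99L, prepared = PREP)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$params, p2$params)
  p3 <- sample_psa(CFG, n_draws = 20, seed = 100L, prepared = PREP)
  expect_false(identical(p1$samples$icer, p3$samples$icer))
  # drawn age norms keep the non-increasing constraint per draw
  norms <- p1$params[, grep("population_norm_by_age_band",
                            colnames(p1$params))]
  expect_true(all(apply(norms, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(is.finite(p1$samples$icer)))
})

test_that("CEAC is a probability curve, monotone when all draws gain QALYs", {
  p <- sample_psa(CFG, n_draws = 25, seed = 5L, prepared = PREP)
  cc <- ceac(p)
  expect_equal(cc$wtp, seq(0, 50000, by = 2500))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  if (all(p$samples$delta_qaly > 0))
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  expect_error(ceac(p, numeric(0)), "empty")
})

test_that("one-way sensitivity analysis produces ordered finite spreads", {
  osa <- one_way_sa(CFG,
                    parameters = c("costs.ct_reading",
                                   "population.lc_incidence_50_74",
                                   "utilities.pre_progression_by_stage.stage_I",
                                   "scan_round2.p_regular.negative"),
                    prepared = PREP)
  expect_equal(nrow(osa), 4)
  expect_true(all(is.finite(osa$spread)))
  expect_true(all(diff(osa$spread) <= 0))  # sorted descending
  # a pure cost parameter moves the ICER monotonically
  row <- osa[osa$parameter == "costs.ct_reading", ]
  expect_lt(row$icer_low, row$icer_high)
})
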