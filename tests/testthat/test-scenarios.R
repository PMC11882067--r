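test_that("the scenario registry mirrors the published table", {
  reg <- scenario_registry()
  expect_length(reg, 35)
  expect_true("Base-case analysis" %in% names(reg))
  expect_true("Time horizon (5 years)" %in% names(reg))
  expect_identical(names(reg), unname(vapply(reg, `[[`, "", "name")))
})

test_that("unknown scenario names fail with the registry listed", {
  expect_error(run_scenario(CFG, "No such scenario", prepared = PREP),
               "Base-case analysis")
})

test_that("the base-case scenario equals the base-case run", {
  res <- run_scenario(CFG, "Base-case analysis", prepared = PREP)
  expect_equal(res$incremental$icer_per_qaly, BC$incremental$icer_per_qaly,
               tolerance = 1e-12)
})

test_that("multiplier overrides scale the configured value", {
  res <- run_scenario(CFG, "Doubled diagnostic costs for both arms",
                      prepared = PREP)
  expect_equal(res$config$costs$diag_screen, 2 * CFG$costs$diag_screen)
  expect_equal(res$config$costs$diag_clinical, 2 * CFG$costs$diag_clinical)
  expect_gt(res$incremental$icer_per_qaly, BC$incremental$icer_per_qaly)
})

test_that("uptake changes scale both arms' incrementals", {
  hi <- run_scenario(CFG, "Screening uptake rate (75%)", prepared = PREP)
  expect_gt(hi$incremental$delta_qaly, 2 * BC$incremental$delta_qaly)
  expect_gt(hi$incremental$delta_cost, 2 * BC$incremental$delta_cost)
})

test_that("cheaper AI reading lowers the ICER monotonically", {
  i15 <- run_scenario(CFG, "AI-assisted imaging reading - report reading - EUR 15",
                      prepared = PREP)$incremental$icer_per_qaly
  i10 <- run_scenario(CFG, "AI-assisted imaging reading - report reading - EUR 10",
                      prepared = PREP)$incremental$icer_per_qaly
  i5 <- run_scenario(CFG, "AI-assisted imaging reading - report reading - EUR 5",
                     prepared = PREP)$incremental$icer_per_qaly
  expect_true(i5 < i10 && i10 < i15 && i15 < BC$incremental$icer_per_qaly)
})

test_that("missed-survival levers order the ICER as published", {
  icer_of <- function(name) run_scenario(CFG, name,
                                         prepared = PREP)$incremental$icer_per_qaly
  gp <- icer_of("Overall survival for missed individuals follows general population")
  s1 <- icer_of("Overall survival for missed individuals follows stage I patients")
  s3 <- icer_of("Overall survival for missed individuals follows stage III patients")
  s4 <- icer_of("Overall survival for missed individuals follows stage IV patients")
  base <- BC$incremental$icer_per_qaly
  expect_true(gp > s1 && s1 > base && base > s3 && s3 > s4)
})

test_that("doubling background mortality raises the ICER", {
  res <- run_scenario(CFG, "Increase background mortality by 100%",
                      prepared = PREP)
  expect_gt(res$incremental$icer_per_qaly, BC$incremental$icer_per_qaly)
})

test_that("run_all_scenarios returns one well-formed row per registry entry", {
  sc <- run_all_scenarios(CFG, prepared = PREP)
  expect_equal(nrow(sc), 35)
  expect_true(all(c("scenario", "delta_cost", "delta_qaly", "icer",
                    "icer_label") %in% names(sc)))
  expect_true(all(is.finite(sc$icer)))
  base_row <- sc[sc$scenario == "Base-case analysis", ]
  expect_equal(base_row$icer, BC$incremental$icer_per_qaly, tolerance = 1e-9)
})
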