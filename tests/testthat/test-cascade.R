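test_that("screening-round outcomes conserve the cohort", {
  cfg <- base_case_config()
  ro <- run_screening_round(10000, cfg$scan_round1)
  expect_equal(ro$n_true_positive + ro$n_false_positive, ro$n_positive,
               tolerance = 1e-12)
  expect_equal(sum(ro$detected_by_stage), ro$n_true_positive, tolerance = 1e-12)
  expect_equal(ro$n_continuing,
               ro$n_scanned - ro$n_true_positive - ro$n_interval_cancers,
               tolerance = 1e-12)
  expect_true(ro$n_followup_scans > 0)
  expect_error(run_screening_round(-1, cfg$scan_round1), "non-negative")
})

test_that("interval cancers are annualised over the round interval", {
  cfg <- base_case_config()
  r2 <- cfg$scan_round2
  ro <- run_screening_round(1000, r2)
  fn_annual <- 1 - (1 - r2$p_negative_truth[["false_negative"]])^(1 / r2$interval_years)
  expect_equal(ro$n_interval_cancers,
               (1000 - ro$n_positive) * fn_annual, tolerance = 1e-12)
})

test_that("cascade audit and diagnosis streams are internally consistent", {
  casc <- BC$cascade
  expect_equal(casc$n_rounds, 17)
  audit <- cascade_audit(casc)
  expect_equal(nrow(audit), 17)
  expect_true(all(audit$scans > 0))
  # scans shrink as detected/interval cancers and deaths leave the pool
  expect_true(all(diff(audit$scans) < 0))
  # lifetime cancers balance across arms up to the missed individuals
  expect_equal(sum(casc$screen_diag) - sum(casc$noscreen_diag),
               sum(casc$missed), tolerance = 1e-9 * sum(casc$screen_diag))
})

test_that("recruitment costs arise once, at programme start", {
  casc <- BC$cascade
  cfg <- base_case_config()
  elig <- compute_eligible_population(cfg$population)
  expect_equal(casc$recruitment[1],
               elig$n_age_eligible * cfg$costs$sms_cost +
                 elig$n_participants * cfg$costs$phone_cost, tolerance = 1e-9)
  expect_true(all(casc$recruitment[-1] == 0))
})

test_that("screening stops at the maximum screening age", {
  cfg <- apply_override(base_case_config(), "population.mean_start_age", 70)
  casc <- run_cascade(cfg, lt = PREP$lt)
  expect_equal(casc$n_rounds, 5)  # ages 70..74 only
})
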