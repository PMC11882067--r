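sched_for <- function(stage, n_cycles = 168, mode = "disease") {
  cfg <- base_case_config()
  transition_schedule(PREP$fits, stage, cfg, PREP$lt,
                      entry_age = cfg$population$mean_start_age,
                      n_cycles = n_cycles, mode = mode)
}

test_that("transition schedules are valid probability systems", {
  for (st in c("stage_I", "stage_IV")) {
    sc <- sched_for(st)
    expect_true(all(sc$p_death_pre >= 0 & sc$p_death_pre <= 1))
    expect_true(all(sc$p_prog >= 0))
    expect_true(all(sc$p_prog + pmax(sc$p_death_pre, sc$p_death_post) <= 1 + 1e-12))
    expect_true(all(sc$lc_share_pre >= 0 & sc$lc_share_pre <= 1))
  }
  # stage I recovery: progression stops after the recovery horizon
  sc1 <- sched_for("stage_I")
  expect_true(all(sc1$recovered[21:168]))
  expect_false(any(sc1$recovered[1:20]))
  expect_true(all(sc1$p_prog[21:168] == 0))
  expect_true(all(sc1$lc_share_pre[21:168] == 0))
  # stage IV never recovers
  expect_false(any(sched_for("stage_IV")$recovered))
})

test_that("general-population mode carries background mortality only", {
  sc <- sched_for("stage_II", mode = "general_population")
  expect_true(all(sc$p_prog == 0))
  expect_true(all(sc$lc_share_pre == 0 & sc$lc_share_post == 0))
  expect_equal(sc$p_death_pre, sc$p_death_post)
})

test_that("Markov cohort conserves persons to 1e-9", {
  cfg <- base_case_config()
  sc <- sched_for("stage_III")
  K <- length(sc$p_death_pre)
  tr <- run_cohort(1000, sc, rep(0.67, K), rep(0.66, K), cfg$costs,
                   "stage_III", cfg$economics)
  totals <- rowSums(tr$occupancy)
  expect_true(all(abs(totals - 1000) < 1e-9 * 1000))
  # dead-state occupancy at each cycle start equals accumulated deaths
  expect_equal(unname(tr$occupancy[K, "dead"]), sum(tr$new_deaths[1:(K - 1)]),
               tolerance = 1e-12)
  expect_true(all(tr$lc_deaths_by_cycle <= tr$new_deaths + 1e-12))
})

test_that("utilities of one make QALYs equal life years", {
  cfg <- base_case_config()
  sc <- sched_for("stage_II")
  K <- length(sc$p_death_pre)
  tr <- run_cohort(500, sc, rep(1, K), rep(1, K), NULL, "stage_II",
                   cfg$economics)
  expect_equal(tr$qaly_disc, tr$ly_disc, tolerance = 1e-12)
  expect_equal(tr$qaly_undisc, tr$ly_undisc, tolerance = 1e-12)
})

test_that("zero discounting equates discounted and undiscounted totals", {
  cfg <- base_case_config()
  cfg <- apply_override(cfg, "economics.discount_rate_effects", 0)
  cfg <- apply_override(cfg, "economics.discount_rate_costs", 0)
  sc <- sched_for("stage_II")
  K <- length(sc$p_death_pre)
  tr <- run_cohort(500, sc, rep(0.8, K), rep(0.7, K), cfg$costs, "stage_II",
                   cfg$economics)
  expect_equal(tr$ly_disc, tr$ly_undisc, tolerance = 1e-12)
  expect_equal(tr$qaly_disc, tr$qaly_undisc, tolerance = 1e-12)
})

test_that("utility_at applies the norm cap, recovery and stage IV disutility", {
  u <- base_case_config()$utilities
  expect_equal(utility_at("stage_I", "pre", 62, 2, u), 0.67)  # cap binds
  expect_equal(utility_at("stage_I", "pre", 55, 2, u), 0.71)  # cap slack
  expect_equal(utility_at("stage_I", "pre", 62, 6, u), 0.67)  # recovered: norm
  expect_equal(utility_at("stage_I", "pre", 55, 6, u), 0.77)
  u2 <- u
  u2$post_progression_disutility_stage4 <- 0.1
  expect_equal(utility_at("stage_IV", "post", 62, 1, u2, recovery = FALSE),
               0.66 - 0.1 - 0)  # cap 0.67 slack at 0.66, then disutility
})

test_that("the vectorised stage engine matches the reference cohort loop", {
  cfg <- base_case_config()
  eco <- cfg$economics
  M <- eco$horizon_years * 12 / eco$cycle_months
  for (st in c("stage_I", "stage_IV")) {
    sc <- transition_schedule(PREP$fits, st, cfg, PREP$lt,
                              entry_age = cfg$population$mean_start_age,
                              n_cycles = M)
    ages <- cfg$population$mean_start_age +
      (seq_len(M) - 1) * eco$cycle_months / 12
    ypd <- (seq_len(M) - 1) * eco$cycle_months / 12
    u_pre <- utility_at(st, "pre", ages, ypd, cfg$utilities)
    u_post <- utility_at(st, "post", ages, ypd, cfg$utilities,
                         recovery = FALSE)
    ref <- run_cohort(1234, sc, u_pre, u_post, cfg$costs, st, eco)
    fast <- lcscreen:::.run_stage_block(c(1234), st, PREP$fits, cfg, PREP$lt)
    expect_equal(fast$ly_disc, ref$ly_disc, tolerance = 1e-8)
    expect_equal(fast$qaly_disc, ref$qaly_disc, tolerance = 1e-8)
    expect_equal(fast$lc_deaths, ref$lc_deaths, tolerance = 1e-8)
    expect_equal(fast$cost_by_phase, ref$cost_by_phase, tolerance = 1e-8)
  }
})

test_that("cancer-free accrual matches a hand-built annuity", {
  cfg <- base_case_config()
  lt0 <- generate_life_table(q50 = 1e-12, log_slope = 0)  # (almost) immortal
  out <- accrue_cancer_free(1000, numeric(0), cfg, lt0, horizon_cycles = 8)
  # 2 years alive at norm 0.77, discounted quarterly
  df <- (1.035)^-((0:7) * 0.25)
  expect_equal(out$ly_disc, sum(1000 * 0.25 * df), tolerance = 1e-6)
  expect_equal(out$qaly_disc, sum(1000 * 0.25 * 0.77 * df), tolerance = 1e-6)
  expect_equal(out$ly_undisc, 2000, tolerance = 1e-6)
})
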