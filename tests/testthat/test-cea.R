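test_that("ICER dominance labels follow the quadrant", {
  expect_equal(icer(100, 2)$label, "icer")
  expect_equal(icer(-100, 2)$label, "dominant")
  expect_equal(icer(100, -2)$label, "dominated")
  expect_equal(icer(100, 0)$label, "undefined")
  expect_true(is.na(icer(100, 0)$icer))
  expect_equal(icer(278971940, 50679)$icer, 278971940 / 50679)
})

test_that("NMB sign is equivalent to the ICER-vs-WTP comparison", {
  set.seed(7)
  for (i in 1:200) {
    dc <- runif(1, -1e6, 1e6)
    dq <- runif(1, 0.01, 100)   # positive effects, the informative case
    wtp <- runif(1, 0, 50000)
    v <- nmb(wtp, dq, dc)
    expect_equal(v > 0, dc / dq < wtp, info = sprintf("draw %d", i))
  }
})

test_that("arm totals decompose into stage, missed and cancer-free parts", {
  for (arm in list(BC$screening, BC$no_screening)) {
    expect_equal(arm$ly_total,
                 sum(arm$ly_by_stage) + arm$ly_missed + arm$ly_cancer_free,
                 tolerance = 1e-9)
    expect_equal(arm$qaly_total,
                 sum(arm$qaly_by_stage) + arm$qaly_missed + arm$qaly_cancer_free,
                 tolerance = 1e-9)
    expect_equal(arm$cost_total,
                 arm$cost_recruitment + arm$cost_screening +
                   arm$cost_diagnostic + arm$cost_treatment, tolerance = 1e-9)
    expect_equal(arm$cost_treatment, sum(arm$cost_treatment_by_stage),
                 tolerance = 1e-9)
  }
  # the cancer-free block is identical across arms by construction
  expect_equal(BC$screening$ly_cancer_free, BC$no_screening$ly_cancer_free)
  # QALYs can never exceed LYs (utilities <= 1)
  expect_lt(BC$screening$qaly_total, BC$screening$ly_total)
})

test_that("incremental quantities are internally consistent", {
  inc <- BC$incremental
  expect_equal(inc$icer_per_qaly, inc$delta_cost / inc$delta_qaly)
  expect_equal(inc$icer_per_ly, inc$delta_cost / inc$delta_ly)
  expect_equal(inc$nmb,
               BC$config$economics$wtp * inc$delta_qaly - inc$delta_cost)
  expect_equal(inc$deaths_averted,
               BC$no_screening$lc_deaths_total - BC$screening$lc_deaths_total)
})

test_that("the CEA report is a readable delimited file", {
  path <- tempfile(fileext = ".csv")
  write_cea_report(BC, path)
  df <- read.csv(path)
  expect_true(all(c("outcome", "screening", "no_screening", "incremental",
                    "incremental_rounded") %in% names(df)))
  expect_gt(nrow(df), 15)
  icer_row <- df[df$outcome == "icer_per_qaly", ]
  expect_equal(icer_row$incremental, BC$incremental$icer_per_qaly)
})
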