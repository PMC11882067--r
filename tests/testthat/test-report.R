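test_that("run_base_case writes the full report bundle", {
  out <- file.path(tempdir(), "lcs-report-test")
  dir.create(out, showWarnings = FALSE)
  res <- run_base_case(out_dir = out)
  expect_s3_class(res, "cea_result")
  for (f in c("base_case.csv", "cascade_audit.csv", "traces.csv",
              "manifest.txt"))
    expect_true(file.exists(file.path(out, f)), info = f)
  bc <- read.csv(file.path(out, "base_case.csv"))
  expect_equal(bc$incremental[bc$outcome == "icer_per_qaly"],
               BC$incremental$icer_per_qaly)
  manifest <- readLines(file.path(out, "manifest.txt"))
  expect_true(any(grepl("config_hash", manifest)))
  unlink(out, recursive = TRUE)
})

test_that("report writers refuse an unwritable output directory", {
  blocker <- tempfile()
  writeLines("x", blocker)  # a plain file: cannot create a directory inside it
  expect_error(run_base_case(out_dir = file.path(blocker, "sub")),
               "not writable")
})

test_that("write_manifest records the configuration fingerprint", {
  path <- tempfile()
  write_manifest(CFG, "unit-test", path, seed = 42)
  lines <- readLines(path)
  expect_true(any(grepl("unit-test", lines)))
  expect_true(any(grepl("seed", lines)))
  # same config, same hash; changed config, different hash
  path2 <- tempfile()
  write_manifest(CFG, "unit-test", path2, seed = 42)
  h <- function(p) grep("config_hash", readLines(p), value = TRUE)
  expect_identical(h(path), h(path2))
  path3 <- tempfile()
  write_manifest(apply_override(CFG, "economics.wtp", 1), "unit-test", path3)
  expect_false(identical(h(path), h(path3)))
})
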