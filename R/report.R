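# Report writers and analysis entry points (the CLI wraps these; see
# inst/scripts/lcscreen.R).

.load_or_base <- function(config_path) {
  if (is.null(config_path)) base_case_config() else load_config(config_path)
}

.check_outdir <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  invisible(out_dir)
}

#' Write a run manifest
#'
#' Records what was run: a hash of the configuration, seed, timestamp, package
#' version and the analysis requested. Identical manifests on the same
#' platform imply identical numeric outputs (the pipeline is deterministic
#' given config + seed).
#'
#' @param cfg an `lcs_config`.
#' @param analysis label of the analysis performed.
#' @param path output file.
#' @param seed seed used (`NA` for deterministic analyses).
#' @return `path` invisibly.
#' @export
write_manifest <- function(cfg, analysis, path, seed = NA) {
  con <- textConnection("cfg_text", "w", local = TRUE)
  dput(unclass(cfg), con); close(con)
  hash <- sum(utf8ToInt(paste(cfg_text, collapse = "\n")) *
                (seq_along(utf8ToInt(paste(cfg_text, collapse = "\n"))) %% 997 + 1))
  lines <- c(
    sprintf("config_hash: %.0f", hash),
    sprintf("seed: %s", ifelse(is.na(seed), "NA", as.character(seed))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("lcscreen"))),
    sprintf("analysis: %s", analysis))
  writeLines(lines, path)
  invisible(path)
}

#' Run the base case and write its reports
#'
#' Writes the arm-level results table (`base_case.csv`), the per-round
#' cascade audit (`cascade_audit.csv`), per-stage per-arm trace summaries
#' (`traces.csv`) and a run manifest (`manifest.txt`).
#'
#' @param config_path YAML config path; `NULL` for the packaged base case.
#' @param out_dir output directory (created if needed).
#' @return The `cea_result`, invisibly.
#' @export
run_base_case <- function(config_path = NULL, out_dir = ".") {
  cfg <- .load_or_base(config_path)
  .check_outdir(out_dir)
  res <- run_cea(cfg)
  write_cea_report(res, file.path(out_dir, "base_case.csv"))
  utils::write.csv(cascade_audit(res$cascade),
                   file.path(out_dir, "cascade_audit.csv"), row.names = FALSE)
  traces <- do.call(rbind, lapply(c("screening", "no_screening"), function(a) {
    x <- res[[a]]
    data.frame(arm = a, stage = .STAGES,
               diagnoses = as.numeric(x$diagnoses_by_stage),
               lc_deaths = as.numeric(x$lc_deaths_by_stage),
               ly = as.numeric(x$ly_by_stage),
               qaly = as.numeric(x$qaly_by_stage),
               treatment_cost = as.numeric(x$cost_treatment_by_stage))
  }))
  utils::write.csv(traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
  write_manifest(cfg, "base-case", file.path(out_dir, "manifest.txt"))
  invisible(res)
}

#' Run a named uncertainty/scenario analysis and write its reports
#'
#' @param mode one of `"osa"`, `"psa"`, `"ceac"`, `"scenarios"`, `"all"`.
#' @param config_path YAML config path; `NULL` for the packaged base case.
#' @param out_dir output directory.
#' @param draws PSA iterations (psa/ceac/all modes).
#' @param seed PSA seed.
#' @param wtp_grid CEAC willingness-to-pay grid.
#' @return Named list of the objects produced, invisibly.
#' @export
run_analysis <- function(mode = c("osa", "psa", "ceac", "scenarios", "all"),
                         config_path = NULL, out_dir = ".", draws = 1000,
                         seed = 1L, wtp_grid = seq(0, 50000, by = 2500)) {
  mode <- match.arg(mode)
  cfg <- .load_or_base(config_path)
  .check_outdir(out_dir)
  prepared <- prepare_model(cfg)
  out <- list()
  if (mode %in% c("osa", "all")) {
    out$osa <- one_way_sa(cfg, prepared = prepared)
    utils::write.csv(out$osa, file.path(out_dir, "osa_tornado.csv"),
                     row.names = FALSE)
  }
  if (mode %in% c("psa", "ceac", "all")) {
    out$psa <- sample_psa(cfg, n_draws = draws, seed = seed,
                          prepared = prepared)
    utils::write.csv(out$psa$samples, file.path(out_dir, "psa_ce_plane.csv"),
                     row.names = FALSE)
  }
  if (mode %in% c("ceac", "all")) {
    out$ceac <- ceac(out$psa, wtp_grid)
    utils::write.csv(out$ceac, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
  }
  if (mode %in% c("scenarios", "all")) {
    out$scenarios <- run_all_scenarios(cfg, prepared)
    utils::write.csv(out$scenarios, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
  }
  write_manifest(cfg, mode, file.path(out_dir, "manifest.txt"), seed = seed)
  invisible(out)
}
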