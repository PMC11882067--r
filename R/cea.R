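# Arm-level aggregation, incrementals, ICERs and net monetary benefit.

#' Prepare reusable model inputs
#'
#' Builds the life table and the fitted per-stage survival set once, so that
#' sensitivity and scenario analyses that do not touch the survival anchors
#' can reuse them.
#'
#' @param cfg an `lcs_config`.
#' @return A `prepared_model` list with `lt` and `fits`.
#' @export
prepare_model <- function(cfg) {
  lt <- generate_life_table(cfg$life_table$q50, cfg$life_table$log_slope,
                            cfg$life_table$max_age)
  structure(list(lt = lt, fits = fit_survival_set(cfg)),
            class = "prepared_model")
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (euros).
#' @param delta_effect incremental effect (LYs or QALYs).
#' @return List with `icer` (euros per unit effect; `NA` when the effect
#'   difference is zero) and `label` (`"icer"`, `"dominant"` — cheaper and
#'   more effective, `"dominated"` — dearer and less effective, or
#'   `"undefined"`).
#' @export
#' @examples
#' icer(278971940, 50679)   # ~5,505 euros/QALY
icer <- function(delta_cost, delta_effect) {
  if (is.na(delta_effect) || delta_effect == 0)
    return(list(icer = NA_real_, label = "undefined"))
  val <- delta_cost / delta_effect
  label <- if (delta_cost <= 0 && delta_effect > 0) "dominant"
           else if (delta_cost >= 0 && delta_effect < 0) "dominated"
           else "icer"
  list(icer = val, label = label)
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`, computed on unrounded internals.
#'
#' @param wtp willingness-to-pay threshold (euros per QALY, >= 0).
#' @param delta_qaly incremental QALYs.
#' @param delta_cost incremental cost (euros).
#' @return Euros.
#' @export
nmb <- function(wtp, delta_qaly, delta_cost) {
  stopifnot(wtp >= 0)
  wtp * delta_qaly - delta_cost
}

.year_discount <- function(rate, years) (1 + rate)^-(seq_len(years) - 1)

#' Run the full cost-effectiveness analysis
#'
#' Runs the screening cascade, the per-stratum Markov traces for both arms
#' (including missed individuals and cancer-free participants), and aggregates
#' arm totals, incrementals, ICERs and NMB.
#'
#' @param cfg an `lcs_config`.
#' @param prepared optional [prepare_model()] output to reuse.
#' @return A `cea_result`; see [print.cea_result()] and
#'   [write_cea_report()].
#' @export
#' @examples
#' \donttest{
#' res <- run_cea(base_case_config())
#' res$incremental$icer_per_qaly
#' }
run_cea <- function(cfg, prepared = NULL) {
  cfg <- validate_config(unclass(cfg), renorm_warn = FALSE)
  if (is.null(prepared)) prepared <- prepare_model(cfg)
  lt <- prepared$lt
  fits <- prepared$fits
  eco <- cfg$economics
  cpy <- 12 / eco$cycle_months
  M <- eco$horizon_years * cpy

  casc <- run_cascade(cfg, lt)
  yrs <- casc$years
  df_c <- .year_discount(eco$discount_rate_costs, yrs)

  mi <- cfg$survival_inputs$missed_survival
  missed_mode <- if (mi == "general_population") "general_population" else "disease"
  missed_stage <- if (missed_mode == "disease") mi else "stage_II"

  stage_block <- function(entries, stage) {
    .run_stage_block(entries, stage, fits, cfg, lt, costs = cfg$costs,
                     horizon_cycles = M)
  }
  arm <- function(diag_matrix, missed_entries = NULL) {
    by_stage <- lapply(.STAGES, function(s) stage_block(diag_matrix[, s], s))
    names(by_stage) <- .STAGES
    missed <- NULL
    if (!is.null(missed_entries) && sum(abs(missed_entries)) > 0) {
      missed <- .run_stage_block(missed_entries, missed_stage, fits, cfg, lt,
                                 costs = NULL, mode = missed_mode,
                                 recovery = isTRUE(cfg$survival_inputs$missed_recovery),
                                 horizon_cycles = M)
    }
    list(by_stage = by_stage, missed = missed)
  }

  s_arm <- arm(casc$screen_diag)
  n_arm <- arm(casc$noscreen_diag, casc$missed)

  removals <- rowSums(casc$screen_diag)
  cf <- accrue_cancer_free(casc$eligible$n_smoking_eligible, removals, cfg, lt,
                           horizon_cycles = M)

  collect <- function(a, diag_matrix, missed_entries, diag_cost_stream,
                      recruitment = 0, screening_cost = 0) {
    tr_stage <- vapply(a$by_stage, function(b) sum(b$cost_by_phase), 0)
    ly_stage <- vapply(a$by_stage, `[[`, 0, "ly_disc")
    qa_stage <- vapply(a$by_stage, `[[`, 0, "qaly_disc")
    deaths_stage <- vapply(a$by_stage, `[[`, 0, "lc_deaths")
    m <- a$missed
    list(
      diagnoses_by_stage = colSums(diag_matrix),
      diagnoses_missed = if (is.null(missed_entries)) 0 else sum(missed_entries),
      diagnoses_total = sum(diag_matrix) +
        (if (is.null(missed_entries)) 0 else sum(missed_entries)),
      lc_deaths_by_stage = deaths_stage,
      lc_deaths_missed = if (is.null(m)) 0 else m$lc_deaths,
      lc_deaths_total = sum(deaths_stage) + (if (is.null(m)) 0 else m$lc_deaths),
      ly_by_stage = ly_stage,
      ly_missed = if (is.null(m)) 0 else m$ly_disc,
      ly_cancer_free = cf$ly_disc,
      ly_total = sum(ly_stage) + (if (is.null(m)) 0 else m$ly_disc) + cf$ly_disc,
      qaly_by_stage = qa_stage,
      qaly_missed = if (is.null(m)) 0 else m$qaly_disc,
      qaly_cancer_free = cf$qaly_disc,
      qaly_total = sum(qa_stage) + (if (is.null(m)) 0 else m$qaly_disc) +
        cf$qaly_disc,
      cost_recruitment = recruitment,
      cost_screening = screening_cost,
      cost_diagnostic = sum(diag_cost_stream * df_c),
      cost_treatment_by_stage = tr_stage,
      cost_treatment = sum(tr_stage),
      cost_total = recruitment + screening_cost +
        sum(diag_cost_stream * df_c) + sum(tr_stage)
    )
  }

  screening <- collect(s_arm, casc$screen_diag, NULL, casc$diag_cost_screen_arm,
                       recruitment = sum(casc$recruitment * df_c),
                       screening_cost = sum(casc$screening_cost * df_c))
  no_screening <- collect(n_arm, casc$noscreen_diag, casc$missed,
                          casc$diag_cost_noscreen_arm)

  inc <- list(
    delta_cost = screening$cost_total - no_screening$cost_total,
    delta_ly = screening$ly_total - no_screening$ly_total,
    delta_qaly = screening$qaly_total - no_screening$qaly_total,
    deaths_averted = no_screening$lc_deaths_total - screening$lc_deaths_total,
    early_stage_gain = sum(screening$diagnoses_by_stage[c("stage_I", "stage_II")]) -
      sum(no_screening$diagnoses_by_stage[c("stage_I", "stage_II")]),
    late_stage_averted = sum(no_screening$diagnoses_by_stage[c("stage_III", "stage_IV")]) -
      sum(screening$diagnoses_by_stage[c("stage_III", "stage_IV")]),
    missed_individuals = no_screening$diagnoses_missed
  )
  iq <- icer(inc$delta_cost, inc$delta_qaly)
  il <- icer(inc$delta_cost, inc$delta_ly)
  inc$icer_per_qaly <- iq$icer
  inc$icer_per_qaly_label <- iq$label
  inc$icer_per_ly <- il$icer
  inc$icer_per_ly_label <- il$label
  inc$nmb <- nmb(eco$wtp, inc$delta_qaly, inc$delta_cost)

  structure(list(screening = screening, no_screening = no_screening,
                 incremental = inc, cascade = casc, config = cfg),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  i <- x$incremental
  eur <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat("<cea_result> screening vs no screening\n")
  cat(sprintf("  incremental cost   : %s EUR\n", eur(i$delta_cost)))
  cat(sprintf("  incremental LYs    : %s\n", eur(i$delta_ly)))
  cat(sprintf("  incremental QALYs  : %s\n", eur(i$delta_qaly)))
  cat(sprintf("  ICER per LY        : %s EUR\n", eur(i$icer_per_ly)))
  cat(sprintf("  ICER per QALY      : %s EUR (%s)\n", eur(i$icer_per_qaly),
              i$icer_per_qaly_label))
  cat(sprintf("  NMB at WTP %s  : %s EUR\n",
              eur(x$config$economics$wtp), eur(i$nmb)))
  cat(sprintf("  deaths averted     : %s\n", eur(i$deaths_averted)))
  cat(sprintf("  early-stage gain   : %s diagnoses\n", eur(i$early_stage_gain)))
  invisible(x)
}

#' Write the arm-level results report
#'
#' Emits a delimited (CSV) report shaped like the base-case results table:
#' one row per outcome (diagnoses, lung-cancer deaths, life years, QALYs,
#' cost components) with screening, no-screening and incremental columns,
#' euros unrounded plus a display-rounded column.
#'
#' @param res a `cea_result`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_cea_report <- function(res, path) {
  s <- res$screening; n <- res$no_screening
  row <- function(outcome, sv, nv) data.frame(
    outcome = outcome, screening = sv, no_screening = nv,
    incremental = sv - nv, incremental_rounded = round(sv - nv))
  rows <- list(
    row("diagnoses_total", s$diagnoses_total, n$diagnoses_total))
  for (st in .STAGES)
    rows <- c(rows, list(row(paste0("diagnoses_", st),
                             s$diagnoses_by_stage[[st]],
                             n$diagnoses_by_stage[[st]])))
  rows <- c(rows, list(
    row("diagnoses_missed", s$diagnoses_missed, n$diagnoses_missed),
    row("lc_deaths_total", s$lc_deaths_total, n$lc_deaths_total),
    row("ly_total", s$ly_total, n$ly_total),
    row("ly_cancer_free", s$ly_cancer_free, n$ly_cancer_free),
    row("qaly_total", s$qaly_total, n$qaly_total),
    row("qaly_cancer_free", s$qaly_cancer_free, n$qaly_cancer_free),
    row("cost_recruitment", s$cost_recruitment, n$cost_recruitment),
    row("cost_screening", s$cost_screening, n$cost_screening),
    row("cost_diagnostic", s$cost_diagnostic, n$cost_diagnostic),
    row("cost_treatment", s$cost_treatment, n$cost_treatment)))
  for (st in .STAGES)
    rows <- c(rows, list(row(paste0("cost_treatment_", st),
                             s$cost_treatment_by_stage[[st]],
                             n$cost_treatment_by_stage[[st]])))
  rows <- c(rows, list(row("cost_total", s$cost_total, n$cost_total)))
  df <- do.call(rbind, rows)
  i <- res$incremental
  extra <- data.frame(outcome = c("icer_per_qaly", "icer_per_ly", "nmb"),
                      screening = NA, no_screening = NA,
                      incremental = c(i$icer_per_qaly, i$icer_per_ly, i$nmb),
                      incremental_rounded = round(c(i$icer_per_qaly,
                                                    i$icer_per_ly, i$nmb)))
  write.csv(rbind(df, extra), path, row.names = FALSE)
  invisible(path)
}
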