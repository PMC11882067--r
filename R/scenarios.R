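# Declarative scenario registry: one named config transformation per row of
# the published scenario-analysis table, plus runners.

.scenario <- function(name, overrides = list(), note = "") {
  list(name = name, overrides = overrides, note = note)
}

.build_registry <- function() {
  reg <- list(
    .scenario("Base-case analysis"),
    .scenario("Screening uptake rate (25%)",
              list("population.uptake_rate" = 0.25)),
    .scenario("Screening uptake rate (75%)",
              list("population.uptake_rate" = 0.75)),
    .scenario("Mean age of the screening participants (55 years)",
              list("population.mean_start_age" = 55)),
    .scenario("Mean age of the screening participants (60 years)",
              list("population.mean_start_age" = 60)),
    .scenario("Mean age of the screening participants (65 years)",
              list("population.mean_start_age" = 65)),
    .scenario("Mean age of the screening participants (70 years)",
              list("population.mean_start_age" = 70)),
    .scenario("Time horizon (5 years)",
              list("economics.horizon_years" = 5)),
    .scenario("Time horizon (10 years)",
              list("economics.horizon_years" = 10)),
    .scenario("Time horizon (15 years)",
              list("economics.horizon_years" = 15)),
    .scenario("Number of screening rounds (3 rounds)",
              list("economics.n_rounds" = 3)),
    .scenario("Number of screening rounds (5 rounds)",
              list("economics.n_rounds" = 5)),
    .scenario("Number of screening rounds (10 rounds)",
              list("economics.n_rounds" = 10)),
    .scenario("Number of screening rounds (15 rounds)",
              list("economics.n_rounds" = 15)),
    .scenario("Discount rates (cost: 0%, health outcome: 0%)",
              list("economics.discount_rate_costs" = 0,
                   "economics.discount_rate_effects" = 0)),
    .scenario("Discount rates (cost: 6%, health outcome: 6%)",
              list("economics.discount_rate_costs" = 0.06,
                   "economics.discount_rate_effects" = 0.06)),
    .scenario("Progressed stage IV patients incur a disutility of 0.1",
              list("utilities.post_progression_disutility_stage4" = 0.1)),
    .scenario("Increase background mortality by 100%",
              list("life_table.mortality_multiplier" = 2)),
    .scenario("LC incidence in population aged 50-74 years increase by 20%",
              list("population.lc_incidence_50_74" = "x1.2")),
    .scenario("LC incidence in population aged 50-74 years increase by 50%",
              list("population.lc_incidence_50_74" = "x1.5")),
    .scenario("LC incidence in population aged 50-74 years increase by 100%",
              list("population.lc_incidence_50_74" = "x2")),
    .scenario("Overall survival for missed individuals follows general population",
              list("survival_inputs.missed_survival" = "general_population")),
    .scenario("Overall survival for missed individuals follows stage I patients",
              list("survival_inputs.missed_survival" = "stage_I")),
    .scenario("Overall survival for missed individuals follows stage III patients",
              list("survival_inputs.missed_survival" = "stage_III")),
    .scenario("Overall survival for missed individuals follows stage IV patients",
              list("survival_inputs.missed_survival" = "stage_IV")),
    .scenario("AI-assisted imaging reading - report reading - EUR 15",
              list("costs.ct_reading" = 15)),
    .scenario("AI-assisted imaging reading - report reading - EUR 10",
              list("costs.ct_reading" = 10)),
    .scenario("AI-assisted imaging reading - report reading - EUR 5",
              list("costs.ct_reading" = 5)),
    .scenario("Doubled diagnostic costs for both arms",
              list("costs.diag_screen" = "x2",
                   "costs.diag_clinical" = "x2")),
    .scenario("Increase the first-line treatments costs by 50%",
              list("costs.first_line_per_cycle_by_stage" = "x1.5")),
    .scenario("Increase the second-line treatments costs by 50%",
              list("costs.second_line_by_stage" = "x1.5")),
    .scenario("Increase both the first- and second-line treatments costs by 50%",
              list("costs.first_line_per_cycle_by_stage" = "x1.5",
                   "costs.second_line_by_stage" = "x1.5")),
    .scenario("Increase the first-line treatments costs for stage I LC patients by 50%",
              list("costs.first_line_per_cycle_by_stage.stage_I" = "x1.5"),
              note = "published row duplicates another row's values; implemented per its label"),
    .scenario("Increase the first-line treatments costs for stage IV LC patients by 50%",
              list("costs.first_line_per_cycle_by_stage.stage_IV" = "x1.5"),
              note = "published row duplicates another row's values; implemented per its label"),
    .scenario("Increase the first-line treatments costs for stage III and IV LC patients by 50%",
              list("costs.first_line_per_cycle_by_stage.stage_III" = "x1.5",
                   "costs.first_line_per_cycle_by_stage.stage_IV" = "x1.5"),
              note = "published row duplicates another row's values; implemented per its label")
  )
  names(reg) <- vapply(reg, `[[`, "", "name")
  reg
}

#' Scenario registry
#'
#' One entry per row of the published scenario-analysis table (base case
#' included as an empty override).
#'
#' @return Named list of scenario specs (`name`, `overrides`, `note`).
#' @export
scenario_registry <- function() .build_registry()

# apply one scenario's overrides; string values "x<f>" multiply the current
# value(s) by f, so multiplier scenarios track whatever base config is passed
.apply_scenario <- function(cfg, spec) {
  c2 <- cfg
  for (p in names(spec$overrides)) {
    v <- spec$overrides[[p]]
    if (is.character(v) && grepl("^x[0-9.]+$", v)) {
      cur <- .get_path(unclass(c2), p)
      v <- unlist(cur) * as.numeric(sub("^x", "", v))
    }
    c2 <- apply_override(c2, p, v)
  }
  c2
}

#' Run one named scenario
#'
#' @param cfg base `lcs_config`.
#' @param name scenario name as registered (see [scenario_registry()]).
#' @param prepared optional [prepare_model()] output reused when the scenario
#'   does not alter survival or life-table inputs.
#' @return A `cea_result` with `$scenario` set to the name.
#' @export
run_scenario <- function(cfg, name, prepared = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; registered scenarios:\n  ",
         paste(names(reg), collapse = "\n  "), call. = FALSE)
  spec <- reg[[name]]
  c2 <- .apply_scenario(cfg, spec)
  # survival anchors never change across scenarios; the life table does when
  # the multiplier moves, which prepare_model() handles via config.
  touches_lt <- any(grepl("^life_table", names(spec$overrides)))
  prep <- if (is.null(prepared) || touches_lt) prepare_model(c2) else prepared
  res <- run_cea(c2, prep)
  res$scenario <- name
  res
}

#' Run every registered scenario
#'
#' @param cfg base `lcs_config`.
#' @param prepared optional [prepare_model()] output.
#' @return Data frame shaped like the published scenario table: scenario name,
#'   per-arm total costs and QALYs, incremental costs and QALYs, ICER
#'   (euros/QALY) and its dominance label. Per-row failures are reported as
#'   `NA` rows with the error message in `note`.
#' @export
run_all_scenarios <- function(cfg, prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_model(cfg)
  reg <- scenario_registry()
  rows <- lapply(names(reg), function(nm) {
    res <- try(run_scenario(cfg, nm, prepared), silent = TRUE)
    if (inherits(res, "try-error"))
      return(data.frame(scenario = nm, screening_cost = NA, screening_qaly = NA,
                        noscreening_cost = NA, noscreening_qaly = NA,
                        delta_cost = NA, delta_qaly = NA, icer = NA,
                        icer_label = NA,
                        note = conditionMessage(attr(res, "condition"))))
    i <- res$incremental
    data.frame(scenario = nm,
               screening_cost = res$screening$cost_total,
               screening_qaly = res$screening$qaly_total,
               noscreening_cost = res$no_screening$cost_total,
               noscreening_qaly = res$no_screening$qaly_total,
               delta_cost = i$delta_cost, delta_qaly = i$delta_qaly,
               icer = i$icer_per_qaly, icer_label = i$icer_per_qaly_label,
               note = reg[[nm]]$note)
  })
  do.call(rbind, rows)
}
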