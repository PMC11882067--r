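# Decision tree: eligibility arithmetic, annual screening rounds
# (regular / indeterminate / positive pathways, true and false positives,
# interval cancers), clinical presentation in both arms, and the
# missed-individuals construction.
#
# Reconciliation of screen-detection probabilities with the annual incidence:
# screening detects prevalent plus anticipated disease at the published
# per-round rates, so participants accrue more lifetime diagnoses than the
# incidence mechanism alone would give. That excess is exactly the
# missed-individuals count followed (undiagnosed) in the no-screening arm,
# so lifetime cancers balance across arms up to that gap.

#' Eligibility arithmetic
#'
#' Expected-value cohort arithmetic (fractional persons, no rounding):
#' age-eligible = total population x fraction aged 50-74; smoking-eligible =
#' age-eligible x smoking rate; participants = smoking-eligible x uptake.
#'
#' @param pop the `population` section of an `lcs_config`.
#' @return List with `n_age_eligible`, `n_smoking_eligible`, `n_participants`.
#' @export
#' @examples
#' compute_eligible_population(base_case_config()$population)
compute_eligible_population <- function(pop) {
  n_age <- pop$total_population * pop$frac_age_50_74
  n_smoke <- n_age * pop$smoking_rate
  n_part <- n_smoke * pop$uptake_rate
  list(n_age_eligible = n_age, n_smoking_eligible = n_smoke,
       n_participants = n_part)
}

#' Outcome of one screening round
#'
#' Applies one round's scan-outcome probabilities to a cohort: indeterminate
#' regular scans receive one follow-up scan in the same round; positives are
#' direct positives plus follow-up positives, split into true/false positives;
#' negatives split into true negatives (who continue) and false negatives
#' (interval cancers presenting clinically before the next round, annualised
#' over the round's `interval_years`); true positives are allocated to stages
#' by the round's screen stage distribution.
#'
#' @param cohort persons scanned (>= 0; fractional persons allowed).
#' @param probs one of `cfg$scan_round1` / `cfg$scan_round2`.
#' @return A `round_outcome` list: `n_scanned`, `n_regular_scans`,
#'   `n_followup_scans`, `n_positive`, `n_true_positive`, `n_false_positive`,
#'   `n_interval_cancers`, `detected_by_stage`, `n_continuing` (before
#'   background deaths).
#' @export
run_screening_round <- function(cohort, probs) {
  if (cohort < 0) stop("cohort must be non-negative", call. = FALSE)
  p_ind <- probs$p_regular[["indeterminate"]]
  followup <- cohort * p_ind
  pos <- cohort * probs$p_regular[["positive"]] +
    followup * probs$p_indeterminate[["positive"]]
  neg <- cohort - pos
  tp <- pos * probs$p_positive_truth[["true_positive"]]
  fp <- pos * probs$p_positive_truth[["false_positive"]]
  fn_interval <- probs$p_negative_truth[["false_negative"]]
  gap <- if (is.null(probs$interval_years)) 1 else probs$interval_years
  fn_annual <- 1 - (1 - fn_interval)^(1 / gap)
  interval <- neg * fn_annual
  detected <- tp * probs$screen_stage_distribution
  structure(list(
    n_scanned = cohort,
    n_regular_scans = cohort,
    n_followup_scans = followup,
    n_positive = pos,
    n_true_positive = tp,
    n_false_positive = fp,
    n_interval_cancers = interval,
    detected_by_stage = detected,
    n_continuing = cohort - tp - interval
  ), class = "round_outcome")
}

# Clinical-presentation mechanism: annual incidence applied to a cancer-free
# alive pool while attained age <= max incidence age. Returns per-year
# diagnoses and the pool trajectory.
.clinical_track <- function(n0, cfg, lt, years, incidence = NULL) {
  pop <- cfg$population
  inc <- if (is.null(incidence)) pop$lc_incidence_50_74 else incidence
  start_age <- pop$mean_start_age
  diag <- numeric(years)
  pool <- numeric(years + 1)
  pool[1] <- n0
  for (t in seq_len(years)) {
    age <- start_age + t - 1
    d <- if (age <= pop$max_screening_age) pool[t] * inc else 0
    diag[t] <- d
    q <- .annual_q(lt, age) * cfg$life_table$mortality_multiplier
    pool[t + 1] <- (pool[t] - d) * (1 - min(q, 1))
  }
  list(diagnoses = diag, pool = pool)
}

#' Run the full two-arm screening cascade
#'
#' Screening arm: participants attend annual rounds (round-1 probabilities in
#' the first round, round-2 thereafter) while rounds remain and age <= the
#' maximum screening age; detected and interval cancers leave the pool;
#' after screening ends participants revert to the clinical-presentation
#' mechanism while age permits. Non-participants follow the clinical
#' mechanism throughout. No-screening arm: the full eligible pool follows the
#' clinical mechanism. Missed individuals are the per-year signed excess of
#' participants' screening-arm cancers over their no-screening counterparts.
#'
#' @param cfg an `lcs_config`.
#' @param lt optional `lcs_life_table` (defaults to the generator with the
#'   config's parameters).
#' @return An `lcs_cascade` list; see Details.
#' @details The returned object carries, per model year: screening-arm
#'   diagnoses by stage (`screen_diag`, years x 4), no-screening diagnoses
#'   by stage (`noscreen_diag`), missed individuals (`missed`), undiscounted
#'   cost streams (`recruitment`, `screening_cost`, `diag_cost_screen_arm`,
#'   `diag_cost_noscreen_arm`), the per-round audit table (`rounds`), and the
#'   eligibility counts (`eligible`).
#' @export
run_cascade <- function(cfg, lt = NULL) {
  pop <- cfg$population
  eco <- cfg$economics
  if (is.null(lt))
    lt <- generate_life_table(cfg$life_table$q50, cfg$life_table$log_slope,
                              cfg$life_table$max_age)
  mult <- cfg$life_table$mortality_multiplier
  elig <- compute_eligible_population(pop)
  P <- elig$n_participants
  NP <- elig$n_smoking_eligible - P
  H <- eco$horizon_years
  start_age <- pop$mean_start_age
  # rounds cannot extend past the maximum screening age
  R <- min(eco$n_rounds, max(0, pop$max_screening_age - start_age + 1))
  years <- min(H, max(R, pop$max_screening_age - start_age + 1))

  screen_diag <- matrix(0, years, 4, dimnames = list(NULL, .STAGES))
  part_cancers <- numeric(years)       # screening-arm participant cancers
  screening_cost <- numeric(years)
  diag_cost_s <- numeric(years)
  rounds <- list()

  p_pool <- P
  for (t in seq_len(years)) {
    age <- start_age + t - 1
    if (t <= R) {
      probs <- if (t == 1) cfg$scan_round1 else cfg$scan_round2
      ro <- run_screening_round(p_pool, probs)
      screen_diag[t, ] <- screen_diag[t, ] + ro$detected_by_stage +
        ro$n_interval_cancers * pop$clinical_stage_distribution
      part_cancers[t] <- ro$n_true_positive + ro$n_interval_cancers
      screening_cost[t] <- (ro$n_regular_scans + ro$n_followup_scans) *
        (cfg$costs$ct_scan_only + cfg$costs$ct_reading)
      diag_cost_s[t] <- (ro$n_true_positive + ro$n_false_positive) *
        cfg$costs$diag_screen +
        ro$n_interval_cancers * cfg$costs$diag_clinical
      ro$round_index <- t
      rounds[[t]] <- ro
      p_pool <- ro$n_continuing
    } else if (age <= pop$max_screening_age) {
      d <- p_pool * pop$lc_incidence_50_74
      screen_diag[t, ] <- screen_diag[t, ] + d * pop$clinical_stage_distribution
      part_cancers[t] <- d
      diag_cost_s[t] <- d * cfg$costs$diag_clinical
      p_pool <- p_pool - d
    }
    q <- min(.annual_q(lt, age) * mult, 1)
    p_pool <- p_pool * (1 - q)
  }

  # non-participants (screening arm) and the full pool (no-screening arm)
  np_track <- .clinical_track(NP, cfg, lt, years)
  ns_track <- .clinical_track(elig$n_smoking_eligible, cfg, lt, years)
  for (t in seq_len(years)) {
    screen_diag[t, ] <- screen_diag[t, ] +
      np_track$diagnoses[t] * pop$clinical_stage_distribution
    diag_cost_s[t] <- diag_cost_s[t] +
      np_track$diagnoses[t] * cfg$costs$diag_clinical
  }
  noscreen_diag <- outer(ns_track$diagnoses, pop$clinical_stage_distribution)
  colnames(noscreen_diag) <- .STAGES
  diag_cost_ns <- ns_track$diagnoses * cfg$costs$diag_clinical

  # missed: participants' screening-arm cancers minus their no-screening
  # counterparts (participants' share of the clinical mechanism)
  part_share <- if (elig$n_smoking_eligible > 0) P / elig$n_smoking_eligible else 0
  missed <- part_cancers - ns_track$diagnoses * part_share

  recruitment <- c(elig$n_age_eligible * cfg$costs$sms_cost +
                     P * cfg$costs$phone_cost, numeric(years - 1))

  structure(list(
    eligible = elig,
    years = years,
    screen_diag = screen_diag,
    noscreen_diag = noscreen_diag,
    missed = missed,
    recruitment = recruitment,
    screening_cost = screening_cost,
    diag_cost_screen_arm = diag_cost_s,
    diag_cost_noscreen_arm = diag_cost_ns,
    rounds = rounds,
    n_rounds = R
  ), class = "lcs_cascade")
}

#' Per-round audit table
#'
#' @param cascade an `lcs_cascade`.
#' @return Data frame with one row per screening round: scans, follow-up
#'   scans, positives, true/false positives, interval cancers, per-stage
#'   detections.
#' @export
cascade_audit <- function(cascade) {
  do.call(rbind, lapply(cascade$rounds, function(ro) {
    data.frame(round = ro$round_index, scans = ro$n_scanned,
               followup_scans = ro$n_followup_scans, positives = ro$n_positive,
               true_positives = ro$n_true_positive,
               false_positives = ro$n_false_positive,
               interval_cancers = ro$n_interval_cancers,
               stage_I = ro$detected_by_stage[[1]],
               stage_II = ro$detected_by_stage[[2]],
               stage_III = ro$detected_by_stage[[3]],
               stage_IV = ro$detected_by_stage[[4]])
  }))
}
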