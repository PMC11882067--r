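# Three-state Markov cohort engine (pre-progression, post-progression, death)
# run per diagnosed stratum (arm x stage x entry year) on 3-month cycles.
#
# Conventions (configurable where noted):
#  * membership counted at cycle start, no half-cycle correction;
#  * per-cycle death probability = max(disease-specific from the stage OS fit,
#    background all-cause on the cycle scale) in both living states;
#  * progression probability = DFS/PFS cycle event probability minus the OS
#    death probability (so the pre-progression exit rate equals the fitted
#    DFS/PFS event rate), clamped to [0, 1 - p_death];
#  * deaths are split into lung-cancer vs background deaths by hazard share;
#  * stage I/II patients still progression-free after `recovery_years` are
#    clinically recovered: progression stops, mortality reverts to background,
#    utility becomes the age norm, and subsequent deaths are background
#    deaths. Missed individuals are untreated and never recover.

#' Build a per-cycle transition schedule for one stratum
#'
#' @param fits output of [fit_survival_set()].
#' @param stage stage label (`"stage_I"` .. `"stage_IV"`).
#' @param cfg an `lcs_config`.
#' @param lt an `lcs_life_table`.
#' @param entry_age age at diagnosis (years).
#' @param n_cycles schedule length.
#' @param recovery apply the stage I/II clinical-recovery rule.
#' @param mode `"disease"` (default) or `"general_population"` (background
#'   mortality only, no progression; the missed-individuals scenario lever).
#' @return A `transition_schedule` list of per-cycle vectors: `p_death_pre`,
#'   `p_prog`, `p_death_post`, `lc_share_pre`, `lc_share_post`, `recovered`.
#' @export
transition_schedule <- function(fits, stage, cfg, lt, entry_age, n_cycles,
                                recovery = stage %in% c("stage_I", "stage_II"),
                                mode = "disease") {
  cm <- cfg$economics$cycle_months
  ages <- entry_age + (seq_len(n_cycles) - 1) * cm / 12
  q <- pmin(.annual_q(lt, ages) * cfg$life_table$mortality_multiplier, 1)
  p_bg <- annual_to_cycle(q, cm)
  if (mode == "general_population") {
    zero <- numeric(n_cycles)
    return(structure(list(p_death_pre = p_bg, p_prog = zero, p_death_post = p_bg,
                          lc_share_pre = zero, lc_share_post = zero,
                          recovered = rep(FALSE, n_cycles)),
                     class = "transition_schedule"))
  }
  p_os <- cycle_event_probs(fits$os[[stage]], cm, n_cycles)
  p_dfs <- cycle_event_probs(fits$dfs[[stage]], cm, n_cycles)
  p_death <- pmax(p_os, p_bg)
  p_prog <- pmin(pmax(p_dfs - p_os, 0), 1 - p_death)
  lc_share_pre <- .lc_hazard_share(p_death, p_bg)
  # progressed patients die of their cancer while the disease hazard
  # dominates; once the background floor binds, deaths are background-paced
  lc_share_post <- as.numeric(p_os > p_bg)
  rec <- rep(FALSE, n_cycles)
  if (isTRUE(recovery)) {
    k_rec <- cfg$utilities$recovery_years * 12 / cm
    rec[seq_len(n_cycles) - 1 >= k_rec] <- TRUE
  }
  p_death_pre <- ifelse(rec, p_bg, p_death)
  structure(list(
    p_death_pre = p_death_pre,
    p_prog = ifelse(rec, 0, p_prog),
    p_death_post = p_death,
    lc_share_pre = ifelse(rec, 0, lc_share_pre),
    lc_share_post = lc_share_post,
    recovered = rec
  ), class = "transition_schedule")
}

# fraction of deaths attributable to lung cancer: 1 - h_bg / h_total on the
# hazard scale (log-survival ratio)
.lc_hazard_share <- function(p_total, p_bg) {
  share <- numeric(length(p_total))
  pos <- p_total > 0 & p_total < 1
  share[pos] <- 1 - log1p(-p_bg[pos]) / log1p(-p_total[pos])
  share[p_total >= 1] <- 1 - p_bg[p_total >= 1]  # degenerate cycle
  pmin(pmax(share, 0), 1)
}

#' State/stage utility with the population-norm cap and recovery rule
#'
#' Returns the published stage/state utility capped at the age-band population
#' norm; clinically recovered stage I/II pre-progression patients (>= the
#' recovery horizon since diagnosis) receive the norm itself.
#'
#' @param stage stage label.
#' @param state `"pre"` or `"post"`.
#' @param age attained age in years.
#' @param years_since_diagnosis elapsed years.
#' @param utilities the `utilities` section of an `lcs_config`.
#' @param recovery whether the recovery rule applies to this patient.
#' @return Utility value in \[0, 1\]. Vectorised over `age` /
#'   `years_since_diagnosis`.
#' @export
#' @examples
#' u <- base_case_config()$utilities
#' utility_at("stage_I", "pre", 62, 2, u)   # cap binds: min(0.71, 0.67)
#' utility_at("stage_I", "pre", 62, 6, u)   # recovered: norm 0.67
utility_at <- function(stage, state, age, years_since_diagnosis, utilities,
                       recovery = stage %in% c("stage_I", "stage_II")) {
  norm <- .norm_at_age(age, utilities$population_norm_by_age_band)
  base <- if (state == "pre") utilities$pre_progression_by_stage[[stage]]
          else utilities$post_progression_by_stage[[stage]]
  u <- pmin(base, norm)
  if (state == "pre" && isTRUE(recovery)) {
    rec <- years_since_diagnosis >= utilities$recovery_years
    u[rec] <- norm[rec]
  }
  if (state == "post" && stage == "stage_IV")
    u <- pmax(u - utilities$post_progression_disutility_stage4, 0)
  u
}

.norm_at_age <- function(age, norms) {
  idx <- findInterval(age, c(-Inf, 60, 70, 80))
  unname(norms[idx])
}

#' Run one Markov cohort stratum (reference implementation)
#'
#' Straightforward per-cycle loop for a single entry cohort. The pipeline uses
#' an equivalent vectorised engine; this function is the readable reference
#' and the unit under property tests.
#'
#' @param entry persons entering the pre-progression state at cycle 0.
#' @param schedule a [transition_schedule()] covering the horizon.
#' @param utility_pre,utility_post per-cycle utilities (numeric vectors the
#'   same length as the schedule).
#' @param costs the `costs` section of an `lcs_config`; `NULL` accrues no
#'   costs (missed individuals).
#' @param stage stage label (for stage-specific cost rows).
#' @param econ the `economics` section of an `lcs_config`.
#' @param entry_time_years model time of diagnosis (discounting offset).
#' @return A `markov_trace` list: per-cycle occupancy matrix, new
#'   progressions/deaths, and accumulated discounted/undiscounted totals
#'   (`ly_disc`, `qaly_disc`, `ly_undisc`, `lc_deaths`, `cost_by_phase`).
#' @export
run_cohort <- function(entry, schedule, utility_pre, utility_post, costs,
                       stage, econ, entry_time_years = 0) {
  K <- length(schedule$p_death_pre)
  if (length(utility_pre) != K || length(utility_post) != K)
    stop("utility schedule shorter than horizon", call. = FALSE)
  if (entry < 0) stop("entry cohort must be non-negative", call. = FALSE)
  cyl <- econ$cycle_months / 12
  df_e <- (1 + econ$discount_rate_effects)^-(entry_time_years + (seq_len(K) - 1) * cyl)
  df_c <- (1 + econ$discount_rate_costs)^-(entry_time_years + (seq_len(K) - 1) * cyl)

  occ <- matrix(0, K, 3, dimnames = list(NULL, c("pre", "post", "dead")))
  new_prog <- new_death <- lc_death <- numeric(K)
  pre <- entry; post <- 0; dead <- 0
  fl_cycles <- 4 * 3 / econ$cycle_months          # first-line: first year
  ac1_end <- 2 * 12 / econ$cycle_months           # aftercare epoch 1: <= 2y
  ac_end <- if (is.null(costs)) 0 else costs$aftercare_years * 12 / econ$cycle_months
  phase <- c(first_line = 0, aftercare_pre = 0, second_line = 0,
             aftercare_post = 0, end_of_life = 0)
  ly_disc <- qaly_disc <- ly_undisc <- qaly_undisc <- 0
  hcc <- isTRUE(econ$half_cycle_correction)

  for (k in seq_len(K)) {
    occ[k, ] <- c(pre, post, dead)
    d_pre <- pre * schedule$p_death_pre[k]
    prog <- pre * schedule$p_prog[k]
    d_post <- post * schedule$p_death_post[k]
    lc <- d_pre * schedule$lc_share_pre[k] + d_post * schedule$lc_share_post[k]
    # half-cycle correction averages start- and end-of-cycle membership
    w_pre <- if (hcc) pre - (d_pre + prog) / 2 else pre
    w_post <- if (hcc) post + (prog - d_post) / 2 else post
    ly <- (w_pre + w_post) * cyl
    qa <- (w_pre * utility_pre[k] + w_post * utility_post[k]) * cyl
    ly_disc <- ly_disc + ly * df_e[k]
    qaly_disc <- qaly_disc + qa * df_e[k]
    ly_undisc <- ly_undisc + ly
    qaly_undisc <- qaly_undisc + qa
    if (!is.null(costs)) {
      fl <- if (k <= fl_cycles) pre * costs$first_line_per_cycle_by_stage[[stage]] else 0
      ac <- if (k <= ac1_end) pre * costs$aftercare_preprog_first2y
            else if (k <= ac_end) pre * costs$aftercare_preprog_after2y else 0
      sl <- prog * costs$second_line_by_stage[[stage]]
      ap <- post * costs$aftercare_postprog_per_cycle
      eo <- lc * costs$end_of_life_by_stage[[stage]]
      phase <- phase + c(fl, ac, sl, ap, eo) * df_c[k]
    }
    new_prog[k] <- prog; new_death[k] <- d_pre + d_post; lc_death[k] <- lc
    pre <- pre - d_pre - prog
    post <- post + prog - d_post
    dead <- dead + d_pre + d_post
  }
  structure(list(occupancy = occ, new_progressions = new_prog,
                 new_deaths = new_death, lc_deaths_by_cycle = lc_death,
                 ly_disc = ly_disc, qaly_disc = qaly_disc,
                 ly_undisc = ly_undisc, qaly_undisc = qaly_undisc,
                 lc_deaths = sum(lc_death), deaths = sum(new_death),
                 cost_by_phase = phase, entry = entry),
            class = "markov_trace")
}

# Fast engine: all entry years of one (arm, stage) block at once.
# entries: vector of cohort sizes entering at model years 1..n (diagnosis at
# model time (t-1) years). Returns the same accumulated totals as run_cohort
# summed over entry years.
.run_stage_block <- function(entries, stage, fits, cfg, lt,
                             costs = cfg$costs, mode = "disease",
                             recovery = NULL, horizon_cycles = NULL) {
  eco <- cfg$economics
  cm <- eco$cycle_months
  cpy <- 12 / cm                             # cycles per year
  M <- if (is.null(horizon_cycles)) eco$horizon_years * cpy else horizon_cycles
  nyr <- length(entries)
  if (is.null(recovery)) recovery <- stage %in% c("stage_I", "stage_II")
  cyl <- cm / 12
  start_age <- cfg$population$mean_start_age

  # disease cycle probabilities indexed by cycles since diagnosis (k = 1..M)
  if (mode == "disease") {
    p_os <- cycle_event_probs(fits$os[[stage]], cm, M)
    p_dfs <- cycle_event_probs(fits$dfs[[stage]], cm, M)
  } else {
    p_os <- p_dfs <- numeric(M)
  }
  # background mortality indexed by model cycle (m = 1..M)
  ages_m <- start_age + (seq_len(M) - 1) * cyl
  q <- pmin(.annual_q(lt, ages_m) * cfg$life_table$mortality_multiplier, 1)
  p_bg_m <- annual_to_cycle(q, cm)
  norm_m <- .norm_at_age(ages_m, cfg$utilities$population_norm_by_age_band)
  k_rec <- cfg$utilities$recovery_years * cpy

  u_pre_stage <- cfg$utilities$pre_progression_by_stage[[stage]]
  u_post_stage <- cfg$utilities$post_progression_by_stage[[stage]]
  disu <- if (stage == "stage_IV") cfg$utilities$post_progression_disutility_stage4 else 0

  df_e <- (1 + eco$discount_rate_effects)^-((seq_len(M) - 1) * cyl)
  df_c <- (1 + eco$discount_rate_costs)^-((seq_len(M) - 1) * cyl)

  fl_rate <- if (is.null(costs)) 0 else costs$first_line_per_cycle_by_stage[[stage]]
  sl_rate <- if (is.null(costs)) 0 else costs$second_line_by_stage[[stage]]
  eol_rate <- if (is.null(costs)) 0 else costs$end_of_life_by_stage[[stage]]
  ac1 <- if (is.null(costs)) 0 else costs$aftercare_preprog_first2y
  ac2 <- if (is.null(costs)) 0 else costs$aftercare_preprog_after2y
  acp <- if (is.null(costs)) 0 else costs$aftercare_postprog_per_cycle
  ac_end <- if (is.null(costs)) 0 else costs$aftercare_years * cpy

  pre <- post <- numeric(nyr)
  entry_cycle <- (seq_len(nyr) - 1) * cpy + 1      # model cycle of diagnosis
  ly_disc <- qaly_disc <- ly_undisc <- qaly_undisc <- 0
  phase <- c(first_line = 0, aftercare_pre = 0, second_line = 0,
             aftercare_post = 0, end_of_life = 0)
  lc_deaths <- deaths <- 0
  hcc <- isTRUE(eco$half_cycle_correction)

  for (m in seq_len(M)) {
    inject <- which(entry_cycle == m)
    if (length(inject)) pre[inject] <- pre[inject] + entries[inject]
    k <- m - entry_cycle + 1                        # cycles since diagnosis
    active <- k >= 1
    if (!any(active)) next
    ka <- k[active]
    pd <- pmax(p_os[ka], p_bg_m[m])
    pp <- pmin(pmax(p_dfs[ka] - p_os[ka], 0), 1 - pd)
    lcsh_pre <- .lc_hazard_share(pd, rep(p_bg_m[m], length(ka)))
    # progressed patients die of their cancer while the disease hazard
    # dominates; once the background floor binds, deaths are background-paced
    lcsh <- as.numeric(p_os[ka] > p_bg_m[m])
    rec <- recovery & (ka - 1 >= k_rec) & mode == "disease"
    pd_pre <- ifelse(rec, p_bg_m[m], pd)
    pp <- ifelse(rec, 0, pp)
    lcsh_pre <- ifelse(rec, 0, lcsh_pre)
    if (mode == "general_population") { pd[] <- p_bg_m[m]; pd_pre[] <- p_bg_m[m]
                                        pp[] <- 0; lcsh[] <- 0; lcsh_pre[] <- 0 }

    pre_a <- pre[active]; post_a <- post[active]
    u_pre <- ifelse(rec, norm_m[m], pmin(u_pre_stage, norm_m[m]))
    u_post <- pmax(pmin(u_post_stage, norm_m[m]) - disu, 0)

    d_pre <- pre_a * pd_pre
    prog <- pre_a * pp
    d_post <- post_a * pd
    lc <- sum(d_pre * lcsh_pre + d_post * lcsh)

    # half-cycle correction averages start- and end-of-cycle membership
    w_pre <- if (hcc) pre_a - (d_pre + prog) / 2 else pre_a
    w_post <- if (hcc) post_a + (prog - d_post) / 2 else post_a
    ly <- sum(w_pre + w_post) * cyl
    qa <- sum(w_pre * u_pre + w_post * u_post) * cyl
    ly_disc <- ly_disc + ly * df_e[m]; ly_undisc <- ly_undisc + ly
    qaly_disc <- qaly_disc + qa * df_e[m]; qaly_undisc <- qaly_undisc + qa

    if (!is.null(costs)) {
      fl <- sum(pre_a[ka <= cpy]) * fl_rate                # first year
      acst <- sum(pre_a[ka <= 2 * cpy]) * ac1 +
              sum(pre_a[ka > 2 * cpy & ka <= ac_end]) * ac2
      phase <- phase + c(fl, acst, sum(prog) * sl_rate, sum(post_a) * acp,
                         lc * eol_rate) * df_c[m]
    }
    lc_deaths <- lc_deaths + lc
    deaths <- deaths + sum(d_pre) + sum(d_post)
    pre[active] <- pre_a - d_pre - prog
    post[active] <- post_a + prog - d_post
  }
  list(ly_disc = ly_disc, qaly_disc = qaly_disc, ly_undisc = ly_undisc,
       qaly_undisc = qaly_undisc, lc_deaths = lc_deaths, deaths = deaths,
       cost_by_phase = phase, entries = sum(entries))
}

#' Accrue life years and QALYs for lung-cancer-free participants
#'
#' Runs the eligible cohort forward on the cycle grid under background
#' mortality, removing new diagnoses at year starts (the same removal schedule
#' is used in both arms, which makes the cancer-free block identical across
#' arms by construction). QALYs use the age-band population norms.
#'
#' @param n0 initial cancer-free cohort.
#' @param removals_by_year diagnoses removed at the start of each model year.
#' @param cfg an `lcs_config`.
#' @param lt an `lcs_life_table`.
#' @param horizon_cycles optional truncation.
#' @return List with `ly_disc`, `qaly_disc`, `ly_undisc`, `qaly_undisc`.
#' @export
accrue_cancer_free <- function(n0, removals_by_year, cfg, lt,
                               horizon_cycles = NULL) {
  eco <- cfg$economics
  cm <- eco$cycle_months
  cpy <- 12 / cm
  M <- if (is.null(horizon_cycles)) eco$horizon_years * cpy else horizon_cycles
  cyl <- cm / 12
  ages <- cfg$population$mean_start_age + (seq_len(M) - 1) * cyl
  q <- pmin(.annual_q(lt, ages) * cfg$life_table$mortality_multiplier, 1)
  p_bg <- annual_to_cycle(q, cm)
  norm <- .norm_at_age(ages, cfg$utilities$population_norm_by_age_band)
  df_e <- (1 + eco$discount_rate_effects)^-((seq_len(M) - 1) * cyl)

  pool <- n0
  ly_disc <- qaly_disc <- ly_undisc <- qaly_undisc <- 0
  hcc <- isTRUE(eco$half_cycle_correction)
  for (m in seq_len(M)) {
    if ((m - 1) %% cpy == 0) {
      yr <- (m - 1) %/% cpy + 1
      if (yr <= length(removals_by_year)) pool <- pool - removals_by_year[yr]
      pool <- max(pool, 0)
    }
    w <- if (hcc) pool * (1 - p_bg[m] / 2) else pool
    ly <- w * cyl
    qa <- w * norm[m] * cyl
    ly_disc <- ly_disc + ly * df_e[m]; ly_undisc <- ly_undisc + ly
    qaly_disc <- qaly_disc + qa * df_e[m]; qaly_undisc <- qaly_undisc + qa
    pool <- pool * (1 - p_bg[m])
  }
  list(ly_disc = ly_disc, qaly_disc = qaly_disc,
       ly_undisc = ly_undisc, qaly_undisc = qaly_undisc)
}
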