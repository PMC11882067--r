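# One-way (tornado) and probabilistic sensitivity analysis, CE plane, CEAC.

# scalar parameters and their PSA families (Dirichlet simplexes are handled
# group-wise via .SIMPLEX_PATHS). Discount rates, horizon, rounds and the
# survival anchors are Fixed and never perturbed.
.PSA_SCALARS <- c(
  "population.total_population" = "gamma",
  "population.frac_age_50_74" = "beta",
  "population.smoking_rate" = "beta",
  "population.uptake_rate" = "beta",
  "population.lc_incidence_50_74" = "gamma",
  "utilities.pre_progression_by_stage.stage_I" = "beta",
  "utilities.pre_progression_by_stage.stage_II" = "beta",
  "utilities.pre_progression_by_stage.stage_III" = "beta",
  "utilities.pre_progression_by_stage.stage_IV" = "beta",
  "utilities.post_progression_by_stage.stage_I" = "beta",
  "utilities.post_progression_by_stage.stage_II" = "beta",
  "utilities.post_progression_by_stage.stage_III" = "beta",
  "utilities.post_progression_by_stage.stage_IV" = "beta",
  "utilities.population_norm_by_age_band.50-59" = "beta",
  "utilities.population_norm_by_age_band.60-69" = "beta",
  "utilities.population_norm_by_age_band.70-79" = "beta",
  "utilities.population_norm_by_age_band.80+" = "beta",
  "costs.sms_cost" = "gamma",
  "costs.phone_cost" = "gamma",
  "costs.ct_scan_only" = "gamma",
  "costs.ct_reading" = "gamma",
  "costs.diag_screen" = "gamma",
  "costs.diag_clinical" = "gamma",
  "costs.first_line_per_cycle_by_stage.stage_I" = "gamma",
  "costs.first_line_per_cycle_by_stage.stage_II" = "gamma",
  "costs.first_line_per_cycle_by_stage.stage_III" = "gamma",
  "costs.first_line_per_cycle_by_stage.stage_IV" = "gamma",
  "costs.aftercare_preprog_first2y" = "gamma",
  "costs.aftercare_preprog_after2y" = "gamma",
  "costs.second_line_by_stage.stage_I" = "gamma",
  "costs.second_line_by_stage.stage_II" = "gamma",
  "costs.second_line_by_stage.stage_III" = "gamma",
  "costs.second_line_by_stage.stage_IV" = "gamma",
  "costs.aftercare_postprog_per_cycle" = "gamma",
  "costs.end_of_life_by_stage.stage_I" = "gamma",
  "costs.end_of_life_by_stage.stage_II" = "gamma",
  "costs.end_of_life_by_stage.stage_III" = "gamma",
  "costs.end_of_life_by_stage.stage_IV" = "gamma",
  "life_table.mortality_multiplier" = "gamma"
)

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full model with each parameter individually moved down/up by
#' `perturbation` (simplex components are renormalised within their group).
#' Entries are sorted by ICER spread, descending.
#'
#' @param cfg an `lcs_config`.
#' @param parameters dotted parameter names; default: every non-Fixed scalar
#'   plus every simplex component.
#' @param perturbation fractional change (default 0.20).
#' @param prepared optional [prepare_model()] output.
#' @return Data frame: `parameter`, `low`, `high` (parameter values),
#'   `icer_low`, `icer_high`, `spread`. Per-parameter failures are recorded
#'   as `NA` rows, not fatal.
#' @export
one_way_sa <- function(cfg, parameters = NULL, perturbation = 0.20,
                       prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_model(cfg)
  if (is.null(parameters)) {
    simplex_comps <- unlist(lapply(.SIMPLEX_PATHS, function(sp) {
      v <- .get_path(unclass(cfg), sp)
      paste(sp, names(v), sep = ".")
    }))
    parameters <- c(names(.PSA_SCALARS), simplex_comps)
  }
  run_at <- function(path, value) {
    res <- try({
      c2 <- apply_override(cfg, path, value)
      run_cea(c2, prepared)$incremental$icer_per_qaly
    }, silent = TRUE)
    if (inherits(res, "try-error")) NA_real_ else res
  }
  rows <- lapply(parameters, function(p) {
    base <- .get_path(unclass(cfg), sub("\\.([^.]+)$", "", p))
    comp <- sub("^.*\\.", "", p)
    v0 <- if (!is.null(base) && !is.list(base) && comp %in% names(base))
      base[[comp]] else .get_path(unclass(cfg), p)
    v0 <- as.numeric(v0)
    lo <- v0 * (1 - perturbation); hi <- v0 * (1 + perturbation)
    # probabilities stay inside [0,1]
    if (grepl("rate|frac|p_|utilit|norm", p)) hi <- min(hi, 1)
    data.frame(parameter = p, low = lo, high = hi,
               icer_low = run_at(p, lo), icer_high = run_at(p, hi))
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_high - out$icer_low)
  out[order(-out$spread), ]
}

.draw_beta <- function(n, mean, se) {
  if (mean <= 0 || mean >= 1) return(rep(mean, n))
  se <- min(se, sqrt(mean * (1 - mean)) * 0.95)
  v <- se^2
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

.draw_gamma <- function(n, mean, se) {
  if (mean <= 0) return(rep(mean, n))
  shape <- (mean / se)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

.draw_dirichlet <- function(n, probs, concentration) {
  a <- probs * concentration
  g <- matrix(rgamma(n * length(a), shape = rep(a, each = n)), nrow = n)
  g / rowSums(g)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter vectors using the published distribution
#' families — Dirichlet for stage distributions and scan-outcome groups, Beta
#' for probabilities and utilities, Gamma for costs and counts (Fixed
#' parameters untouched) — and evaluates the full model per draw. The default
#' dispersion policy is a standard error of 10\% of each mean
#' (`cfg$psa$se_fraction`) with moment-matched Beta/Gamma parameters, and a
#' Dirichlet concentration of `cfg$psa$dirichlet_concentration`.
#'
#' @param cfg an `lcs_config`.
#' @param n_draws number of iterations (published analysis: 1,000).
#' @param seed integer seed; fixed seeds are bit-reproducible.
#' @param prepared optional [prepare_model()] output.
#' @return An `lcs_psa` list: `samples` data frame (draw, delta_cost,
#'   delta_qaly, delta_ly, icer, nmb), `params` matrix of sampled scalar
#'   values, and summary statistics `mean_icer` (mean of per-draw ratios,
#'   mirroring the published summary) and `icer_of_means` (ratio of mean
#'   increments, the preferred estimator).
#' @export
sample_psa <- function(cfg, n_draws = 1000, seed = 1L, prepared = NULL) {
  stopifnot(n_draws >= 1)
  if (is.null(prepared)) prepared <- prepare_model(cfg)
  sef <- cfg$psa$se_fraction
  if (is.null(sef) || sef < 0) stop("invalid dispersion policy", call. = FALSE)
  conc <- cfg$psa$dirichlet_concentration
  set.seed(seed)

  scal <- matrix(NA_real_, n_draws, length(.PSA_SCALARS),
                 dimnames = list(NULL, names(.PSA_SCALARS)))
  for (p in names(.PSA_SCALARS)) {
    v0 <- as.numeric(.get_scalar(cfg, p))
    scal[, p] <- if (sef == 0) rep(v0, n_draws)
      else if (.PSA_SCALARS[[p]] == "beta") .draw_beta(n_draws, v0, sef * v0)
      else .draw_gamma(n_draws, v0, sef * v0)
  }
  # age-norm utilities must stay non-increasing with age band: reorder each
  # draw's four norms (order statistics of the marginal Betas)
  norm_cols <- grep("population_norm_by_age_band", colnames(scal))
  scal[, norm_cols] <- t(apply(scal[, norm_cols, drop = FALSE], 1,
                               sort, decreasing = TRUE))
  simplex_draws <- lapply(.SIMPLEX_PATHS, function(sp) {
    v <- .get_path(unclass(cfg), sp)
    if (sef == 0) matrix(rep(v, each = n_draws), nrow = n_draws,
                         dimnames = list(NULL, names(v)))
    else {
      m <- .draw_dirichlet(n_draws, v, conc)
      colnames(m) <- names(v)
      m
    }
  })
  names(simplex_draws) <- .SIMPLEX_PATHS

  out <- data.frame(draw = seq_len(n_draws), delta_cost = NA_real_,
                    delta_qaly = NA_real_, delta_ly = NA_real_,
                    icer = NA_real_, nmb = NA_real_)
  base <- unclass(cfg)
  for (i in seq_len(n_draws)) {
    c2 <- base
    for (p in names(.PSA_SCALARS)) c2 <- .set_scalar(c2, p, scal[i, p])
    for (sp in .SIMPLEX_PATHS) c2 <- .set_path(c2, sp, simplex_draws[[sp]][i, ])
    res <- run_cea(structure(c2, class = "lcs_config"), prepared)
    inc <- res$incremental
    out$delta_cost[i] <- inc$delta_cost
    out$delta_qaly[i] <- inc$delta_qaly
    out$delta_ly[i] <- inc$delta_ly
    out$icer[i] <- inc$icer_per_qaly
    out$nmb[i] <- inc$nmb
  }
  structure(list(samples = out, params = scal,
                 mean_icer = mean(out$icer, na.rm = TRUE),
                 icer_of_means = sum(out$delta_cost) / sum(out$delta_qaly),
                 icer_ci = quantile(out$icer, c(0.025, 0.975), na.rm = TRUE),
                 seed = seed, n_draws = n_draws),
            class = "lcs_psa")
}

.get_scalar <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- unclass(cfg)
  for (p in parts) x <- if (is.list(x)) x[[p]] else x[[p]]
  x
}

.set_scalar <- function(lst, path, value) .set_path(lst, path, value)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability cost-effective is the
#' fraction of PSA draws with positive net monetary benefit.
#'
#' @param psa an `lcs_psa` (or its `samples` data frame).
#' @param wtp_grid willingness-to-pay values (euros/QALY); non-empty.
#' @return Data frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 2500)) {
  if (!length(wtp_grid)) stop("empty WTP grid", call. = FALSE)
  s <- if (inherits(psa, "lcs_psa")) psa$samples else psa
  if (!nrow(s)) stop("no PSA samples", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(w * s$delta_qaly - s$delta_cost > 0), 0)
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' @export
print.lcs_psa <- function(x, ...) {
  cat(sprintf("<lcs_psa> %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  mean ICER (mean of ratios): %.0f EUR/QALY\n", x$mean_icer))
  cat(sprintf("  ICER of means             : %.0f EUR/QALY\n", x$icer_of_means))
  cat(sprintf("  2.5--97.5%% ICER           : %.0f -- %.0f\n",
              x$icer_ci[1], x$icer_ci[2]))
  invisible(x)
}
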