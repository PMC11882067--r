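# Survival engine: pseudo individual-patient-data reconstruction from
# digitised Kaplan-Meier coordinates, parametric maximum-likelihood fits and
# extrapolation, per-cycle conditional event probabilities, and the
# background-mortality floor.

.FAMILIES <- c(exponential = "exp", weibull = "weibull", gompertz = "gompertz",
               loglogistic = "llogis", lognormal = "lnorm",
               generalized_gamma = "gengamma")

#' Reconstruct pseudo individual-patient data from a digitised KM curve
#'
#' Inverts the Kaplan-Meier estimator interval by interval in the spirit of
#' the published IPD-reconstruction algorithm. When at-risk counts are
#' available they determine interval censoring (assumed uniform within the
#' interval); otherwise a stated initial cohort size is assumed with no
#' censoring before the last coordinate, and all remaining subjects are
#' censored at the final time.
#'
#' @param curve a `digitised_curve` (see [generate_km_curve()] /
#'   [read_curve()]).
#' @param init_n assumed initial number at risk when the curve carries no
#'   at-risk information (default 200).
#' @return A `reconstructed_ipd` list with numeric vectors `time` and
#'   `status` (1 = event, 0 = censored), all times >= 0.
#' @export
reconstruct_ipd <- function(curve, init_n = 200) {
  stopifnot(inherits(curve, "digitised_curve"))
  t <- curve$time
  s <- curve$survival
  if (t[1] > 0) { t <- c(0, t); s <- c(1, s) }
  s[1] <- 1
  if (length(t) < 3) stop("need at least 3 digitised points", call. = FALSE)
  if (any(diff(s) > 1e-9)) stop("survival must be non-increasing", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("survival probabilities must lie in [0,1]",
                               call. = FALSE)

  have_risk <- !is.null(curve$at_risk) && nrow(curve$at_risk) >= 2
  n0 <- if (have_risk) curve$at_risk$n_risk[1] else init_n

  ev_time <- numeric(0); cn_time <- numeric(0)
  n_at <- n0
  for (i in 2:length(t)) {
    if (n_at <= 0) break
    ratio <- if (s[i - 1] > 0) s[i] / s[i - 1] else 0
    d <- round(n_at * (1 - ratio))
    d <- max(0L, min(d, n_at))
    if (d > 0) {
      # spread event times uniformly across the interval
      ev_time <- c(ev_time, t[i - 1] + (t[i] - t[i - 1]) * (seq_len(d) - 0.5) / d)
    }
    n_after_events <- n_at - d
    if (have_risk) {
      # censor down to the observed number at risk at t[i]
      target <- curve$at_risk$n_risk[which.min(abs(curve$at_risk$time - t[i]))]
      c_i <- max(0L, n_after_events - target)
      c_i <- min(c_i, n_after_events)
    } else c_i <- 0L
    if (c_i > 0)
      cn_time <- c(cn_time, t[i - 1] + (t[i] - t[i - 1]) * (seq_len(c_i) - 0.5) / c_i)
    n_at <- n_after_events - c_i
  }
  if (n_at > 0) cn_time <- c(cn_time, rep(max(t), n_at))
  structure(list(time = c(ev_time, cn_time),
                 status = c(rep(1L, length(ev_time)), rep(0L, length(cn_time))),
                 n = n0, source_label = curve$source_label,
                 endpoint = curve$endpoint, stage = curve$stage),
            class = "reconstructed_ipd")
}

#' Pool reconstructed IPD sets
#'
#' Concatenates several reconstructed data sets with weights (default equal),
#' implemented by resampling-free case weighting: each source contributes its
#' subjects with a `weight` column used by the fitter.
#'
#' @param ipds list of `reconstructed_ipd`.
#' @param weights numeric weights, recycled/normalised to the number of sets.
#' @return A pooled `reconstructed_ipd` with a `weight` vector.
#' @export
pool_ipd <- function(ipds, weights = NULL) {
  stopifnot(length(ipds) >= 1)
  if (is.null(weights)) weights <- rep(1, length(ipds))
  weights <- weights / sum(weights) * length(ipds)
  time <- unlist(lapply(ipds, `[[`, "time"))
  status <- unlist(lapply(ipds, `[[`, "status"))
  w <- unlist(mapply(function(x, w) rep(w, length(x$time)), ipds, weights,
                     SIMPLIFY = FALSE))
  structure(list(time = time, status = status, weight = w,
                 n = sum(vapply(ipds, `[[`, 0, "n")),
                 source_label = paste(vapply(ipds, `[[`, "", "source_label"),
                                      collapse = " + "),
                 endpoint = ipds[[1]]$endpoint, stage = ipds[[1]]$stage),
            class = "reconstructed_ipd")
}

#' Kaplan-Meier estimate recomputed from reconstructed IPD
#'
#' @param ipd a `reconstructed_ipd`.
#' @param times evaluation times (months).
#' @return Survival probabilities at `times`.
#' @export
km_from_ipd <- function(ipd, times) {
  fit <- survival::survfit(survival::Surv(ipd$time, ipd$status) ~ 1)
  summary(fit, times = times, extend = TRUE)$surv
}

#' Fit a parametric survival family to reconstructed IPD
#'
#' Maximum-likelihood fit via `flexsurv::flexsurvreg`. Supported families:
#' exponential, weibull, gompertz, loglogistic, lognormal,
#' generalized_gamma.
#'
#' @param ipd a `reconstructed_ipd` (>= 1 event).
#' @param family family name (see above).
#' @param anchor optional list `list(time =, survival =)` recording the
#'   published anchor for this stage/endpoint; the fitted survival at the
#'   anchor time is reported in `anchor_check`.
#' @return A `survival_fit`: family, parameter vector, `aic`, `bic`,
#'   `anchor_check` and the flexsurv object in `$model`.
#' @export
fit_parametric <- function(ipd, family = "exponential", anchor = NULL) {
  stopifnot(inherits(ipd, "reconstructed_ipd"))
  if (sum(ipd$status) < 1) stop("need at least one event to fit", call. = FALSE)
  family <- match.arg(family, names(.FAMILIES))
  dist <- .FAMILIES[[family]]
  dat <- data.frame(time = pmax(ipd$time, 1e-6), status = ipd$status)
  w <- if (!is.null(ipd$weight)) ipd$weight else rep(1, nrow(dat))
  fit <- try(flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1,
                                   data = dat, weights = w, dist = dist),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop(sprintf("fit did not converge: family '%s', %s %s", family,
                 ipd$endpoint, ipd$stage), call. = FALSE)
  pars <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  out <- structure(list(family = family, dist = dist, params = pars,
                        aic = stats::AIC(fit),
                        bic = -2 * fit$loglik + log(sum(ipd$status)) * fit$npars,
                        model = fit, endpoint = ipd$endpoint, stage = ipd$stage,
                        anchor_check = NULL),
                   class = "survival_fit")
  if (!is.null(anchor)) {
    out$anchor_check <- list(time = anchor$time, target = anchor$survival,
                             fitted = survival_at(out, anchor$time))
  }
  out
}

#' Evaluate the fitted survival function
#'
#' @param fit a `survival_fit`.
#' @param t times in months.
#' @return S(t).
#' @export
survival_at <- function(fit, t) {
  p <- as.list(fit$params)
  t <- pmax(t, 0)
  switch(fit$family,
    exponential = exp(-p$rate * t),
    weibull = pweibull(t, p$shape, p$scale, lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, p$shape, p$rate, lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, p$shape, p$scale, lower.tail = FALSE),
    lognormal = plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, p$mu, p$sigma, p$Q,
                                            lower.tail = FALSE)
  )
}

#' Fit several families and select one
#'
#' @param ipd a `reconstructed_ipd`.
#' @param families candidate family names (default all six).
#' @param anchor optional anchor passed to [fit_parametric()].
#' @return Named list of converged `survival_fit`s.
#' @export
fit_families <- function(ipd, families = names(.FAMILIES), anchor = NULL) {
  fits <- list()
  for (f in families) {
    ft <- try(fit_parametric(ipd, f, anchor), silent = TRUE)
    if (!inherits(ft, "try-error")) fits[[f]] <- ft
  }
  if (!length(fits)) stop("no family converged for ", ipd$stage, " ",
                          ipd$endpoint, call. = FALSE)
  fits
}

#' Select a fitted family
#'
#' Returns the lowest-AIC fit by default; `pin` forces a named family (the
#' reconciliation override for mirroring a published distribution choice).
#'
#' @param fits list of `survival_fit` (from [fit_families()]).
#' @param pin optional family name to force.
#' @return A single `survival_fit`.
#' @export
select_fit <- function(fits, pin = NULL) {
  if (!length(fits)) stop("empty fit list", call. = FALSE)
  if (!is.null(pin)) {
    if (is.null(fits[[pin]])) stop("pinned family '", pin, "' not fitted",
                                   call. = FALSE)
    return(fits[[pin]])
  }
  fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]
}

#' Per-cycle conditional event probabilities from a fitted curve
#'
#' `p_k = 1 - S(t_{k+1}) / S(t_k)` on a cycle grid from time zero. Once the
#' fitted survival reaches zero the remaining probabilities are set to 1 with
#' a warning.
#'
#' @param fit a `survival_fit`.
#' @param cycle_months cycle length in months.
#' @param n_cycles number of cycles (>= 1).
#' @return Numeric vector of length `n_cycles`, all in \[0, 1\].
#' @export
cycle_event_probs <- function(fit, cycle_months, n_cycles) {
  stopifnot(n_cycles >= 1)
  grid <- seq(0, n_cycles) * cycle_months
  s <- survival_at(fit, grid)
  p <- numeric(n_cycles)
  dead <- s[-length(s)] <= 0
  if (any(dead)) {
    warning("fitted survival reached zero inside the horizon; remaining cycle probabilities set to 1")
    p[dead] <- 1
  }
  ok <- !dead
  p[ok] <- 1 - s[-1][ok] / s[-length(s)][ok]
  pmin(pmax(p, 0), 1)
}

#' Convert an annual probability to the cycle scale
#' @param p_annual annual probability.
#' @param cycle_months cycle length in months.
#' @return Per-cycle probability `1 - (1 - p)^(cycle_months/12)`.
#' @export
annual_to_cycle <- function(p_annual, cycle_months = 3) {
  1 - (1 - p_annual)^(cycle_months / 12)
}

#' Apply the background-mortality floor
#'
#' Per-cycle death probability is the maximum of the disease-specific
#' probability and the background all-cause probability converted to the
#' cycle scale at each attained age.
#'
#' @param disease_p per-cycle disease-specific death probabilities.
#' @param life_table an `lcs_life_table`.
#' @param age_at_cycle attained age at the start of each cycle (same length
#'   as `disease_p`).
#' @param cycle_months cycle length in months.
#' @return Floored per-cycle death probabilities.
#' @export
apply_mortality_floor <- function(disease_p, life_table, age_at_cycle,
                                  cycle_months = 3) {
  stopifnot(length(disease_p) == length(age_at_cycle))
  if (any(floor(age_at_cycle) > max(life_table$age)) ||
      any(floor(age_at_cycle) < min(life_table$age)))
    stop("age outside life-table range", call. = FALSE)
  q <- .annual_q(life_table, age_at_cycle)
  pmax(disease_p, annual_to_cycle(q, cycle_months))
}

#' Build the per-stage fitted survival set
#'
#' Runs the full curve -> IPD -> fit -> select pipeline on the packaged (or
#' supplied) digitised curves for every stage and endpoint. Fits are cached
#' per anchor set within a session.
#'
#' @param cfg an `lcs_config`.
#' @param curves optional list as returned by [packaged_curves()].
#' @return List with `os` and `dfs`, each four `survival_fit`s named by stage.
#' @export
fit_survival_set <- function(cfg, curves = NULL) {
  si <- cfg$survival_inputs
  key <- paste(c(si$dfs_1y_by_stage, si$os_5y_by_stage, si$curve_n_subjects,
                 unlist(si$pinned_family)), collapse = "|")
  if (is.null(curves) && !is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  cvs <- if (is.null(curves)) packaged_curves(cfg) else curves
  fit_one <- function(curve, anchor_t, anchor_s, pin) {
    ipd <- reconstruct_ipd(curve, init_n = si$curve_n_subjects)
    fits <- fit_families(ipd, families = c("exponential", "weibull",
                                           "loglogistic", "lognormal"),
                         anchor = list(time = anchor_t, survival = anchor_s))
    select_fit(fits, pin = pin)
  }
  os <- dfs <- setNames(vector("list", 4), .STAGES)
  for (i in seq_along(.STAGES)) {
    st <- .STAGES[i]
    os[[i]] <- fit_one(cvs$os[[i]], 60, si$os_5y_by_stage[[i]],
                       si$pinned_family[[paste0("os_", st)]])
    dfs[[i]] <- fit_one(cvs$dfs[[i]], 12, si$dfs_1y_by_stage[[i]],
                        si$pinned_family[[paste0("dfs_", st)]])
  }
  out <- list(os = os, dfs = dfs)
  if (is.null(curves)) .fit_cache[[key]] <- out
  out
}

.fit_cache <- new.env(parent = emptyenv())

#' Write a delimited summary of fitted survival curves
#'
#' @param fits output of [fit_survival_set()].
#' @param path output file (tab-delimited).
#' @return `path` invisibly.
#' @export
write_fit_summary <- function(fits, path) {
  rows <- list()
  for (ep in names(fits)) for (st in names(fits[[ep]])) {
    f <- fits[[ep]][[st]]
    ac <- f$anchor_check
    rows[[length(rows) + 1]] <- data.frame(
      endpoint = ep, stage = st, family = f$family,
      parameters = paste(sprintf("%s=%.6g", names(f$params), f$params),
                         collapse = ";"),
      aic = f$aic, bic = f$bic,
      anchor_time = if (is.null(ac)) NA else ac$time,
      anchor_target = if (is.null(ac)) NA else ac$target,
      anchor_fitted = if (is.null(ac)) NA else ac$fitted)
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
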