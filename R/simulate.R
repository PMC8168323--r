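# Weibull clinical-trial simulator. Generates two-arm (or single-arm)
# trials with uniform staggered accrual, exponential dropout calibrated to a
# target overall censoring fraction, administrative censoring at the end of
# study, a published-style number-at-risk table, and exact digitized step
# coordinates of the Kaplan-Meier curve -- so the whole reconstruction
# pipeline can be validated against known truth.

#' Weibull scale parameter from a target mean
#'
#' Scale \eqn{b} of the Weibull survival function
#' \eqn{S(t) = \exp(-(t/b)^\gamma)} such that the mean survival
#' \eqn{b\,\Gamma(1+1/\gamma)} equals \code{mean}. Equivalently, in the rate
#' parameterization \eqn{S(t) = \exp(-\lambda t^\gamma)},
#' \eqn{\lambda = b^{-\gamma} = (\Gamma(1+1/\gamma)/mean)^\gamma}.
#'
#' @param mean target mean survival (months).
#' @param shape Weibull shape \eqn{\gamma} (> 1 increasing hazard, 1
#'   constant, < 1 decreasing).
#' @return the scale parameter (same units as \code{mean}).
#' @export
weibull_scale_from_mean <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  mean / gamma(1 + 1 / shape)
}

#' Simulation configuration
#'
#' Defaults emulate a two-arm randomized trial: 200 patients per arm,
#' Weibull event times with mean survival 12 months (treatment) and 6 months
#' (control), uniform accrual over 36 months, 24 months of additional
#' follow-up (administrative censoring at study end), exponential dropout
#' calibrated so the overall censoring fraction hits \code{target_censor},
#' and a number-at-risk table every 3 months.
#'
#' @param n_per_arm patients per arm.
#' @param mean_treat,mean_ctrl mean survival in months per arm.
#' @param shape Weibull shape (shared by both arms).
#' @param target_censor target overall censoring fraction (dropout plus
#'   administrative), in (0, 1).
#' @param dropout_rate exponential dropout rate; NULL to calibrate it to
#'   \code{target_censor}.
#' @param recruit_months,followup_months accrual window and post-accrual
#'   follow-up.
#' @param risk_every spacing of the number-at-risk table in months, or NA
#'   for no risk table.
#' @param seed integer seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_per_arm = 200, mean_treat = 12, mean_ctrl = 6,
                       shape = 1, target_censor = 0.30, dropout_rate = NULL,
                       recruit_months = 36, followup_months = 24,
                       risk_every = 3, seed = NULL) {
  stopifnot(n_per_arm >= 1, mean_treat > 0, mean_ctrl > 0, shape > 0,
            target_censor > 0, target_censor < 1,
            recruit_months > 0, followup_months > 0)
  structure(list(n_per_arm = n_per_arm, mean_treat = mean_treat,
                 mean_ctrl = mean_ctrl, shape = shape,
                 target_censor = target_censor, dropout_rate = dropout_rate,
                 recruit_months = recruit_months,
                 followup_months = followup_months,
                 risk_every = risk_every, seed = seed),
            class = "sim_config")
}

#' Calibrate the exponential dropout rate to a target censoring fraction
#'
#' Bisection on the dropout rate \eqn{\lambda^*} until the Monte-Carlo
#' censoring fraction (dropout plus administrative censoring at study end,
#' pooled over the configured arms) is within \code{tol} of
#' \code{target_censor}. Deterministic for a given seed: one set of uniform
#' draws is reused across the bisection, making the fraction monotone in
#' \eqn{\lambda^*}.
#'
#' @param cfg a \code{\link{sim_config}} (its \code{means} may describe one
#'   or two arms; both are pooled equally).
#' @param n_mc Monte-Carlo sample size per evaluation.
#' @param tol calibration tolerance on the censoring fraction.
#' @param means optional override of the arm means (vector).
#' @return the calibrated dropout rate (events per month).
#' @export
calibrate_dropout_rate <- function(cfg, n_mc = 200000L, tol = 0.005,
                                   means = NULL) {
  means <- means %||% c(cfg$mean_treat, cfg$mean_ctrl)
  scales <- vapply(means, weibull_scale_from_mean, 1, shape = cfg$shape)
  with_seed(cfg$seed %||% 1L, {
    arm <- rep_len(seq_along(means), n_mc)
    tev <- stats::rweibull(n_mc, shape = cfg$shape, scale = scales[arm])
    entry <- stats::runif(n_mc, 0, cfg$recruit_months)
    admin <- cfg$recruit_months + cfg$followup_months - entry
    u <- stats::runif(n_mc)
    frac <- function(lam) {
      drop_t <- if (lam <= 0) Inf else -log(u) / lam
      mean(pmin(drop_t, admin) < tev)
    }
    floor_frac <- frac(0)
    if (cfg$target_censor < floor_frac - tol)
      stop_input(sprintf(
        "target censor rate %.3f is below the administrative-censoring floor %.3f",
        cfg$target_censor, floor_frac))
    if (cfg$target_censor <= floor_frac) return(0)
    lo <- 0; hi <- 0.1
    while (frac(hi) < cfg$target_censor && hi < 1e3) hi <- hi * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (frac(mid) < cfg$target_censor) lo <- mid else hi <- mid
      if (abs(frac(mid) - cfg$target_censor) < tol / 2) break
    }
    (lo + hi) / 2
  })
}

#' Exact digitized step coordinates of a Kaplan-Meier curve
#'
#' Exports the coordinates a careful digitizer would extract from the curve
#' of an IPD table: the origin (first time, 1), the top and bottom point of
#' every vertical drop, a point at every number-at-risk report time, and the
#' final point of the curve.
#'
#' @param ipd single-arm IPD table.
#' @param trisk optional report times at which flat points are added.
#' @return coordinate data frame (\code{time}, \code{surv}), sorted by time
#'   with top-of-drop before bottom-of-drop.
#' @export
km_step_points <- function(ipd, trisk = NULL) {
  ipd <- as_ipd(ipd)
  fit <- km_fit(ipd)
  S_prev <- c(1, fit$surv[-length(fit$surv)])
  t0 <- min(ipd$time, 0)
  pts <- rbind(
    data.frame(time = t0, surv = 1),
    data.frame(time = fit$time, surv = S_prev),   # top of each drop
    data.frame(time = fit$time, surv = fit$surv)  # bottom of each drop
  )
  if (!is.null(trisk)) {
    tr <- trisk[trisk <= max(ipd$time)]
    pts <- rbind(pts, data.frame(time = tr, surv = surv_at(fit, tr)))
  }
  t_end <- max(ipd$time)
  pts <- rbind(pts, data.frame(time = t_end, surv = surv_at(fit, t_end)))
  pts <- unique(pts)
  pts <- pts[order(pts$time, -pts$surv), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

# Draw one arm of raw IPD; assumes the RNG state is already set.
draw_arm <- function(n, mean, shape, dropout_rate, recruit, followup, arm) {
  b <- weibull_scale_from_mean(mean, shape)
  tev <- stats::rweibull(n, shape = shape, scale = b)
  entry <- stats::runif(n, 0, recruit)
  admin <- recruit + followup - entry
  tdrop <- if (dropout_rate > 0) stats::rexp(n, dropout_rate) else
    rep(Inf, n)
  obs <- pmin(tev, tdrop, admin)
  data.frame(time = obs, status = as.integer(tev <= pmin(tdrop, admin)),
             arm = arm)
}

# Risk table of an IPD table: counts still under observation at each report
# time; truncated after the last positive count.
risk_table_of <- function(ipd, risk_every, horizon) {
  trisk <- seq(0, horizon - risk_every, by = risk_every)
  nrisk <- vapply(trisk, function(t) sum(ipd$time >= t), 1L)
  keep <- nrisk > 0 & trisk <= max(ipd$time)
  list(trisk = trisk[keep], nrisk = as.integer(nrisk[keep]))
}

#' Simulate a single trial arm with its digitized curve
#'
#' Convenience wrapper around the trial simulator for one arm: Weibull event
#' times, uniform accrual, calibrated exponential dropout plus
#' administrative censoring, the number-at-risk table, and exact digitized
#' step coordinates.
#'
#' @param n patients.
#' @param mean mean survival (months).
#' @param shape Weibull shape.
#' @param target_censor target censoring fraction.
#' @param dropout_rate dropout rate; NULL to calibrate.
#' @param recruit_months,followup_months accrual and follow-up windows.
#' @param risk_every risk-table spacing (months), NA for none.
#' @param seed integer seed.
#' @param arm arm label.
#' @return list with \code{ipd} (true IPD), \code{trisk}, \code{nrisk},
#'   \code{points} (digitized coordinates), \code{dropout_rate},
#'   \code{censor_frac} (realized), \code{km_median} (from the true IPD).
#' @export
simulate_km_arm <- function(n = 200, mean = 12, shape = 1,
                            target_censor = 0.30, dropout_rate = NULL,
                            recruit_months = 36, followup_months = 24,
                            risk_every = 3, seed = NULL, arm = "arm1") {
  cfg <- sim_config(n_per_arm = n, mean_treat = mean, mean_ctrl = mean,
                    shape = shape, target_censor = target_censor,
                    dropout_rate = dropout_rate,
                    recruit_months = recruit_months,
                    followup_months = followup_months,
                    risk_every = risk_every, seed = seed)
  if (is.null(dropout_rate))
    dropout_rate <- calibrate_dropout_rate(cfg, means = mean)
  ipd <- with_seed(seed, draw_arm(n, mean, shape, dropout_rate,
                                  recruit_months, followup_months, arm))
  horizon <- recruit_months + followup_months
  rt <- if (!is.na(risk_every)) risk_table_of(ipd, risk_every, horizon) else
    list(trisk = NULL, nrisk = NULL)
  fit <- km_fit(ipd)
  list(ipd = ipd, trisk = rt$trisk, nrisk = rt$nrisk,
       points = km_step_points(ipd, rt$trisk),
       dropout_rate = dropout_rate,
       censor_frac = mean(ipd$status == 0),
       km_median = quantile_time(fit, 0.5))
}

#' Simulate a two-arm trial with digitized curves
#'
#' Two-arm version of \code{\link{simulate_km_arm}}: the dropout rate is
#' calibrated once, pooled over both arms, so the overall censoring fraction
#' hits the target.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return object of class \code{"km_sim_trial"}: list with \code{arms}
#'   (named list \code{treat}, \code{ctrl}; each as in
#'   \code{\link{simulate_km_arm}}), \code{truth} (true hazard ratio
#'   \code{hr} = treat vs ctrl under the Weibull model, realized censor
#'   fraction, per-arm KM medians of the true IPD), and \code{config}.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dropout_rate <- cfg$dropout_rate %||% calibrate_dropout_rate(cfg)
  horizon <- cfg$recruit_months + cfg$followup_months
  arms <- with_seed(cfg$seed, list(
    treat = draw_arm(cfg$n_per_arm, cfg$mean_treat, cfg$shape, dropout_rate,
                     cfg$recruit_months, cfg$followup_months, "treat"),
    ctrl = draw_arm(cfg$n_per_arm, cfg$mean_ctrl, cfg$shape, dropout_rate,
                    cfg$recruit_months, cfg$followup_months, "ctrl")
  ))
  arms <- lapply(arms, function(ipd) {
    rt <- if (!is.na(cfg$risk_every))
      risk_table_of(ipd, cfg$risk_every, horizon) else
      list(trisk = NULL, nrisk = NULL)
    list(ipd = ipd, trisk = rt$trisk, nrisk = rt$nrisk,
         points = km_step_points(ipd, rt$trisk),
         censor_frac = mean(ipd$status == 0),
         km_median = quantile_time(km_fit(ipd), 0.5))
  })
  b_t <- weibull_scale_from_mean(cfg$mean_treat, cfg$shape)
  b_c <- weibull_scale_from_mean(cfg$mean_ctrl, cfg$shape)
  truth <- list(
    hr = (b_c / b_t)^cfg$shape,   # proportional hazards: shared shape
    censor_frac = mean(c(arms$treat$ipd$status, arms$ctrl$ipd$status) == 0),
    km_median = c(treat = arms$treat$km_median, ctrl = arms$ctrl$km_median),
    dropout_rate = dropout_rate
  )
  structure(list(arms = arms, truth = truth, config = cfg),
            class = "km_sim_trial")
}

#' Gaussian digitization noise
#'
#' Adds independent Gaussian jitter to the times and survival values of
#' digitized coordinates, emulating manual extraction error; survival is
#' clipped to [0, 1] and times to be non-negative. Zero standard deviations
#' leave the points untouched.
#'
#' @param points coordinate data frame.
#' @param sd_t,sd_s jitter standard deviations for time and survival.
#' @param seed integer seed.
#' @return jittered coordinate data frame.
#' @export
digitization_noise <- function(points, sd_t = 0, sd_s = 0, seed = NULL) {
  stopifnot(sd_t >= 0, sd_s >= 0)
  pts <- as_points(points)
  if (sd_t == 0 && sd_s == 0) return(pts)
  with_seed(seed, {
    n <- nrow(pts)
    pts$time <- pmax(0, pts$time + stats::rnorm(n, 0, sd_t))
    pts$surv <- pmin(1, pmax(0, pts$surv + stats::rnorm(n, 0, sd_s)))
  })
  pts
}

#' Six-trial simulation grid
#'
#' A fixed grid of six two-arm trial configurations spanning decreasing
#' (shape 0.8), constant (shape 1) and increasing (shape 1.5) hazards at 30%
#' and 60% censoring, with mean survival 12 vs 6 months (true hazard ratio
#' below 1) except for one null trial (12 vs 12). All use n = 200 per arm
#' and a 3-month risk table.
#'
#' @param seed base seed; trial k uses \code{seed + k}.
#' @return list of six \code{\link{sim_config}} objects.
#' @export
sim_grid <- function(seed = 1L) {
  specs <- list(
    list(shape = 1.0, cens = 0.30, means = c(12, 6)),
    list(shape = 1.0, cens = 0.60, means = c(12, 6)),
    list(shape = 0.8, cens = 0.30, means = c(12, 6)),
    list(shape = 1.0, cens = 0.30, means = c(12, 12)),  # null trial
    list(shape = 1.5, cens = 0.30, means = c(12, 6)),
    list(shape = 1.5, cens = 0.60, means = c(12, 6))
  )
  lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    sim_config(shape = sp$shape, target_censor = sp$cens,
               mean_treat = sp$means[1], mean_ctrl = sp$means[2],
               seed = seed + k)
  })
}
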