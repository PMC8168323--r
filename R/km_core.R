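# Survival-analysis primitives used for accuracy assessment and secondary
# analysis of reconstructed IPD. Product-limit fitting, the log-rank test and
# the proportional-hazards partial likelihood are delegated to the survival
# package; Greenwood standard errors and the Nelson-Aalen cumulative hazard
# are computed from the fitted counts.

#' Kaplan-Meier fit of one arm of IPD
#'
#' Product-limit estimate over the distinct event times of a single-arm IPD
#' table, with at-risk/event/censor counts, Greenwood standard errors and the
#' Nelson-Aalen cumulative hazard. Ties of events and censorings at one time
#' are resolved events-first, the usual survival-analysis convention.
#'
#' @param ipd data frame with columns \code{time} and \code{status}
#'   (1 = event, 0 = censored).
#' @return object of class \code{"km_fit"}: list with \code{time} (distinct
#'   event times), \code{n_risk}, \code{n_event}, \code{n_censor} (censored
#'   in \code{[t_q, t_{q+1})}, trailing censorings attached to the last event
#'   time), \code{surv}, \code{se} (Greenwood), \code{cumhaz}, and \code{n}.
#' @export
km_fit <- function(ipd) {
  ipd <- as_ipd(ipd)
  if (nrow(ipd) == 0L) stop_input("empty IPD table")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = ipd)
  keep <- sf$n.event > 0
  t_q <- sf$time[keep]
  n_q <- sf$n.risk[keep]
  d_q <- sf$n.event[keep]
  S <- sf$surv[keep]
  # censorings between successive event times (before the first event time
  # they reduce n_risk and never enter the estimate)
  c_q <- if (length(t_q)) {
    grp <- findInterval(sf$time, t_q)
    as.integer(vapply(seq_along(t_q),
                      function(q) sum(sf$n.censor[grp == q]), 1))
  } else integer(0)
  gw <- d_q / (n_q * (n_q - d_q))
  gw[!is.finite(gw)] <- NA_real_
  se <- S * sqrt(cumsum(gw))
  se[is.na(se) & S == 0] <- 0
  structure(list(time = t_q, n_risk = n_q, n_event = d_q, n_censor = c_q,
                 surv = S, se = se, cumhaz = cumsum(d_q / n_q),
                 n = nrow(ipd)),
            class = "km_fit")
}

#' Survival probability at given times
#'
#' Right-continuous step lookup on a Kaplan-Meier fit: the estimate at the
#' largest event time not exceeding \code{t}, and 1 before the first event.
#'
#' @param fit a \code{"km_fit"} object.
#' @param t vector of times (>= 0).
#' @return survival probabilities, same length as \code{t}.
#' @export
surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  idx <- findInterval(t, fit$time)
  c(1, fit$surv)[idx + 1L]
}

#' Time at which survival first reaches a given level
#'
#' Smallest event time with estimated survival at or below \code{s}
#' (right-continuous crossing); \code{s = 0.5} gives the median survival
#' time. \code{NA} when the curve never falls to \code{s} (not reached).
#'
#' @param fit a \code{"km_fit"} object.
#' @param s survival levels in (0, 1); may be a vector.
#' @return crossing times (NA where not reached).
#' @export
quantile_time <- function(fit, s) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(s, function(si) {
    hit <- which(fit$surv <= si)
    if (length(hit)) fit$time[hit[1L]] else NA_real_
  }, numeric(1))
}

#' Nelson-Aalen cumulative hazard of a fit
#'
#' @param fit a \code{"km_fit"} object.
#' @return data frame with \code{time} and \code{cumhaz}.
#' @export
cumulative_hazard <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  data.frame(time = fit$time, cumhaz = fit$cumhaz)
}

#' Two-sample log-rank test
#'
#' Standard two-sample log-rank chi-square test (1 df) comparing the event
#' experience of two IPD tables.
#'
#' @param ipd1,ipd2 IPD tables (columns \code{time}, \code{status}).
#' @return list with \code{statistic} and \code{p_value}.
#' @export
logrank_test <- function(ipd1, ipd2) {
  d <- rbind(cbind(as_ipd(ipd1), g = 1L), cbind(as_ipd(ipd2), g = 2L))
  if (sum(d$status) == 0L)
    stop_input("no events in either arm; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, status) ~ g, data = d)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio between two arms
#'
#' Proportional-hazards estimate of the arm-1-versus-arm-2 hazard ratio by
#' Cox partial likelihood with Efron handling of ties (reconstructed IPD has
#' heavy event ties at the drop times, so the tie method matters).
#'
#' @param ipd1,ipd2 IPD tables; the ratio is hazard(arm 1)/hazard(arm 2).
#' @param conf_level confidence level for the Wald interval (default 0.95).
#' @return list with \code{hr}, \code{se_log_hr}, \code{ci} (length 2), and
#'   \code{converged}.
#' @export
hazard_ratio <- function(ipd1, ipd2, conf_level = 0.95) {
  d1 <- as_ipd(ipd1); d2 <- as_ipd(ipd2)
  if (sum(d1$status) < 1L || sum(d2$status) < 1L)
    stop_input("each arm needs at least one event for a hazard ratio")
  d <- rbind(cbind(d1, x = 1), cbind(d2, x = 0))
  cf <- survival::coxph(survival::Surv(time, status) ~ x, data = d,
                        ties = "efron")
  conv <- is.finite(cf$coefficients) && abs(cf$coefficients) < 15
  if (!conv)
    warning("Cox partial likelihood did not converge to a finite hazard ",
            "ratio (monotone likelihood)", call. = FALSE)
  b <- unname(cf$coefficients)
  se <- unname(sqrt(diag(cf$var)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), se_log_hr = se, ci = exp(b + c(-z, z) * se),
       converged = conv)
}

#' Bootstrap percentile confidence interval for the hazard ratio
#'
#' Resamples patients with replacement within each arm, refits the Cox
#' partial likelihood per replicate, and returns the percentile interval of
#' the hazard ratio. Degenerate resamples (an arm without events) are
#' skipped and counted.
#'
#' @param ipd1,ipd2 IPD tables.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed fixing the resampling stream.
#' @param conf_level interval coverage (default 0.95).
#' @return list with \code{ci}, \code{hr} (point estimate on the original
#'   data), \code{B_used}, \code{skipped}.
#' @export
bootstrap_hr_ci <- function(ipd1, ipd2, B = 1000L, seed = NULL,
                            conf_level = 0.95) {
  if (B < 100L) stop_input("B must be at least 100")
  d1 <- as_ipd(ipd1); d2 <- as_ipd(ipd2)
  point <- hazard_ratio(d1, d2)$hr
  hrs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      r1 <- d1[sample.int(nrow(d1), replace = TRUE), ]
      r2 <- d2[sample.int(nrow(d2), replace = TRUE), ]
      if (sum(r1$status) < 1L || sum(r2$status) < 1L) return(NA_real_)
      suppressWarnings(hazard_ratio(r1, r2)$hr)
    }, numeric(1))
  })
  ok <- is.finite(hrs)
  a <- (1 - conf_level) / 2
  list(ci = unname(stats::quantile(hrs[ok], c(a, 1 - a))),
       hr = point, B_used = sum(ok), skipped = sum(!ok))
}

#' Secondary survival analysis report
#'
#' Landmark survival probabilities (with Greenwood SEs and log(-log)
#' confidence intervals) at regular times, survival quantile times for
#' requested levels, the cumulative hazard series, and -- for two arms --
#' the log-rank test and hazard ratio.
#'
#' @param ipd1 IPD table for arm 1.
#' @param ipd2 IPD table for arm 2, or NULL for a one-arm report.
#' @param arms 1 or 2; must be consistent with the inputs.
#' @param interval spacing of the landmark times (default every 6 months).
#' @param s survival levels whose crossing times are reported
#'   (default \code{c(0.5)}; 0.5 is the median survival time).
#' @param conf_level confidence level (default 0.95).
#' @return object of class \code{"survreport"}: per-arm list with
#'   \code{landmark} (time, surv, se, lower, upper), \code{quantiles}
#'   (s, time), \code{cumhaz}; plus \code{logrank} and \code{hazard_ratio}
#'   when \code{arms == 2}.
#' @export
survreport <- function(ipd1, ipd2 = NULL, arms = if (is.null(ipd2)) 1 else 2,
                       interval = 6, s = 0.5, conf_level = 0.95) {
  if (arms == 2 && is.null(ipd2))
    stop_input("arms = 2 requires ipd2")
  if (arms == 1 && !is.null(ipd2))
    stop_input("arms = 1 but two IPD tables supplied")
  ipds <- list(as_ipd(ipd1))
  if (arms == 2) ipds <- c(ipds, list(as_ipd(ipd2)))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_arm <- lapply(ipds, function(d) {
    fit <- km_fit(d)
    t_max <- max(d$time)
    lm_t <- seq(0, t_max, by = interval)
    Sv <- surv_at(fit, lm_t)
    sev <- c(0, fit$se)[findInterval(lm_t, fit$time) + 1L]
    # log(-log) transform keeps the interval inside [0, 1]
    lower <- upper <- rep(NA_real_, length(lm_t))
    okci <- Sv > 0 & Sv < 1 & is.finite(sev) & sev > 0
    se_cl <- sev[okci] / (Sv[okci] * abs(log(Sv[okci])))
    lower[okci] <- Sv[okci]^exp(z * se_cl)
    upper[okci] <- Sv[okci]^exp(-z * se_cl)
    lower[Sv == 1] <- 1; upper[Sv == 1] <- 1
    lower[Sv == 0] <- 0; upper[Sv == 0] <- 0
    list(fit = fit,
         landmark = data.frame(time = lm_t, surv = Sv, se = sev,
                               lower = lower, upper = upper),
         quantiles = data.frame(s = s, time = quantile_time(fit, s)),
         cumhaz = cumulative_hazard(fit))
  })

  rep <- list(arms = arms, per_arm = per_arm, interval = interval, s = s)
  if (arms == 2) {
    rep$logrank <- logrank_test(ipds[[1]], ipds[[2]])
    rep$hazard_ratio <- hazard_ratio(ipds[[1]], ipds[[2]],
                                     conf_level = conf_level)
  }
  class(rep) <- "survreport"
  rep
}

#' @export
print.survreport <- function(x, digits = 3, ...) {
  for (a in seq_along(x$per_arm)) {
    cat("Arm ", a, " landmark survival (every ", x$interval, " units):\n",
        sep = "")
    print(format(x$per_arm[[a]]$landmark, digits = digits),
          row.names = FALSE)
    cat("Survival quantile times:\n")
    print(format(x$per_arm[[a]]$quantiles, digits = digits),
          row.names = FALSE)
    cat("\n")
  }
  if (x$arms == 2) {
    cat(sprintf("Log-rank: chi-square = %.3f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p_value))
    cat(sprintf("Hazard ratio (arm 1 vs arm 2): %.3f [%.3f, %.3f]\n",
                x$hazard_ratio$hr, x$hazard_ratio$ci[1],
                x$hazard_ratio$ci[2]))
  }
  invisible(x)
}

# ---- internal -------------------------------------------------------------

as_ipd <- function(ipd) {
  if (inherits(ipd, "km_recon")) return(ipd$ipd)
  d <- as.data.frame(ipd)
  if (!all(c("time", "status") %in% names(d)))
    stop_input("IPD table needs columns 'time' and 'status'")
  if (any(d$time < 0)) stop_input("negative times in IPD")
  if (!all(d$status %in% c(0, 1)))
    stop_input("status must be 0 (censored) or 1 (event)")
  d[c("time", "status", intersect("arm", names(d)))]
}
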