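# Iterative inversion of a digitized Kaplan-Meier curve into individual
# patient data. Works interval by interval over the published number-at-risk
# table: an initial censoring total per interval is refined until the implied
# number at risk at the next report time matches the published count, under
# box constraints that keep every count non-negative.

#' Initial censoring total for a risk-table interval
#'
#' First guess of the number of patients censored inside interval \eqn{i}:
#' the at-risk count expected at the next report time if nobody had been
#' censored, \code{round(nrisk_i * S_next / S_i)}, minus the published count
#' there, clamped into \code{[0, nrisk_i - nrisk_next]}.
#'
#' @param nrisk_i published number at risk at the start of interval i.
#' @param S_lo_i survival at the first coordinate of interval i.
#' @param S_lo_next survival at the first coordinate of interval i+1.
#' @param nrisk_next published number at risk at the start of interval i+1.
#' @return integer censoring total.
#' @export
init_censor_interval <- function(nrisk_i, S_lo_i, S_lo_next, nrisk_next) {
  if (S_lo_i <= 0)
    stop_input("survival is zero at the start of an interval that still has ",
               "a later at-risk report; degenerate curve")
  est <- round_half_up(nrisk_i * S_lo_next / S_lo_i) - nrisk_next
  max(0, min(est, nrisk_i - nrisk_next))
}

#' Evenly spaced censoring times within an interval
#'
#' Under the constant-censoring-rate assumption the \code{ncensor} censored
#' patients of an interval are placed at the equally spaced interior times
#' \eqn{t_{lo} + m (t_{hi} - t_{lo}) / (ncensor + 1)}, \eqn{m = 1..ncensor}.
#'
#' @param t_lo,t_hi interval endpoints (\code{t_hi > t_lo}).
#' @param ncensor number of censored patients to place.
#' @return numeric vector of length \code{ncensor} (empty when 0).
#' @export
censor_times_for_interval <- function(t_lo, t_hi, ncensor) {
  if (ncensor <= 0) return(numeric(0))
  if (t_hi <= t_lo) stop_input("t_hi must exceed t_lo")
  t_lo + seq_len(ncensor) * (t_hi - t_lo) / (ncensor + 1)
}

# One pass over the coordinates of interval i given a censoring total.
# Walks k = lower..upper maintaining the running product-limit estimate:
#   d_k = round(n_k * (1 - S_k / S_last)), clamped to [0, n_k],
# where S_last is the estimate at the last coordinate with an event (the
# survival has not moved since then, so the factor uses last(k), not k-1);
# censors are consumed by counting placement times in [T_k, T_{k+1}).
# Returns per-coordinate counts plus the state at the interval's end.
sweep_interval <- function(times, survs, n_start, tcensor, t_next,
                           S_last_in) {
  m <- length(times)
  d <- integer(m); cens <- integer(m); n_at <- integer(m)
  S_km <- numeric(m)
  cens_used <- logical(length(tcensor))
  n <- n_start
  S_last <- S_last_in
  for (k in seq_len(m)) {
    n_at[k] <- n
    dk <- 0
    if (n > 0 && S_last > 0 && survs[k] < S_last) {
      dk <- round_half_up(n * (1 - survs[k] / S_last))
      dk <- max(0, min(dk, n))
      if (dk > 0) S_last <- S_last * (1 - dk / n)
    }
    hi <- if (k < m) times[k + 1L] else t_next
    in_gap <- which(!cens_used & tcensor >= times[k] & tcensor < hi)
    ck <- min(length(in_gap), n - dk)   # never censor more than remain
    if (ck > 0) cens_used[in_gap[seq_len(ck)]] <- TRUE
    d[k] <- dk
    cens[k] <- ck
    S_km[k] <- S_last
    n <- n - dk - ck
    if (n < 0) stop("internal error: at-risk count went negative")
  }
  list(d = d, cens = cens, n_at = n_at, S_km = S_km, n_end = n,
       S_last_end = S_last, tcensor_used = tcensor[cens_used])
}

# Fit one interval: refine the censoring total until the implied at-risk
# count at the next report time matches the published one, moving only while
# the box constraints allow (over-estimate: n_end > target and censoring can
# still grow; under-estimate: n_end < target and censoring can still shrink).
# `target` is NA for the last interval (single sweep, no refinement).
fit_interval <- function(times, survs, n_start, t_lo, t_hi, t_next,
                         ncensor_init, cap, target, S_last_in,
                         max_iter = 10000L) {
  ncensor <- max(0, min(ncensor_init, cap))
  best <- NULL
  best_gap <- Inf
  seen <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    tc <- censor_times_for_interval(t_lo, t_hi, ncensor)
    sw <- sweep_interval(times, survs, n_start, tc, t_next, S_last_in)
    gap <- if (is.na(target)) 0 else sw$n_end - target
    if (abs(gap) < best_gap) {
      best_gap <- abs(gap)
      best <- c(sw, list(ncensor = ncensor))
    }
    if (is.na(target) || gap == 0) break
    can_grow <- gap > 0 && ncensor < cap      # condition (6)
    can_shrink <- gap < 0 && ncensor > 0      # condition (7)
    if (!can_grow && !can_shrink) break
    ncensor_new <- max(0, min(ncensor + gap, cap))
    if (ncensor_new == ncensor || ncensor_new %in% seen || iter >= max_iter) {
      if (iter >= max_iter)
        warning("censoring refinement hit max_iter; best iterate kept",
                call. = FALSE)
      break
    }
    seen <- c(seen, ncensor)
    ncensor <- ncensor_new
  }
  best
}

# Initial censoring total for the last interval (no at-risk report closes
# it): the smaller of the censoring volume extrapolated from the average
# censoring rate so far and the patient budget left after the remaining
# events, clamped non-negative.
last_interval_censor_init <- function(n_start, t_lo, t_max, trisk1,
                                      cens_so_far, d_so_far,
                                      endpts = 0, tot_events = NULL) {
  elapsed <- t_lo - trisk1
  rate_term <- if (elapsed > 0) {
    round_half_up(cens_so_far / elapsed * (t_max - t_lo))
  } else {
    Inf   # single-interval curve: no censoring history to extrapolate
  }
  budget <- if (is.null(tot_events)) {
    if (is.infinite(rate_term)) 0 else n_start - endpts
  } else {
    n_start - endpts - max(0, tot_events - d_so_far)
  }
  max(0, min(rate_term, budget))
}

#' Reconstruct individual patient data from a preprocessed K-M curve
#'
#' Runs the iterative product-limit inversion over the risk-table intervals
#' of a preprocessed curve, estimating per-coordinate event, censoring and
#' at-risk counts, and emits one IPD row per patient: events at the drop
#' times of the digitized curve, censorings at their estimated times, and
#' patients still at risk at the end censored at the last coordinate.
#'
#' @param prep a \code{"km_prep"} object from \code{\link{preprocess_curve}}.
#' @param arm arm label attached to every reconstructed row.
#' @param tot_events total number of events, when reported; sharpens the
#'   censoring estimate of the last interval.
#' @param endpts number of patients still at risk at the end of the curve,
#'   when reported (0 when the tail is exhausted).
#' @param max_iter cap on censoring-refinement passes per interval.
#' @return object of class \code{"km_recon"}: list with \code{ipd} (data
#'   frame time/status/arm; status 1 = event, 0 = censored), \code{estimates}
#'   (per-coordinate \code{time}, \code{surv}, \code{n_hat}, \code{d_hat},
#'   \code{cens_hat}, \code{S_km}), \code{audit} (per-interval table:
#'   interval, lower, upper, trisk, nrisk, estimated nrisk, censoring total,
#'   events), and the inputs.
#' @examples
#' sim <- simulate_km_arm(seed = 1)
#' prep <- preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk)
#' rec <- reconstruct_ipd(prep, arm = "treat")
#' head(rec$ipd)
#' summary(rec)
#' @export
reconstruct_ipd <- function(prep, arm = "arm1", tot_events = NULL,
                            endpts = 0, max_iter = 10000L) {
  if (!inherits(prep, "km_prep"))
    stop_input("prep must come from preprocess_curve()")
  pts <- prep$points
  I <- length(prep$trisk)
  n_drops <- sum(diff(pts$surv) < 0) + (pts$surv[1] < 1)
  if (prep$nrisk[1L] < n_drops)
    stop_input("more survival drops than patients at risk; inconsistent input")

  N <- nrow(pts)
  d_hat <- integer(N); cens_hat <- integer(N); n_hat <- integer(N)
  S_km <- numeric(N)
  ncensor <- integer(I)
  event_rows <- list(); censor_rows <- list()

  n <- prep$nrisk[1L]
  S_last <- 1
  t_max <- pts$time[N]

  for (i in seq_len(I)) {
    lo <- prep$lower[i]; up <- prep$upper[i]
    idx <- lo:up
    t_lo <- pts$time[lo]
    last <- i == I
    if (!last) {
      lo_next <- prep$lower[i + 1L]
      t_hi <- pts$time[lo_next]
      target <- prep$nrisk[i + 1L]
      cap <- max(0, n - target)
      nc0 <- init_censor_interval(n, pts$surv[lo], pts$surv[lo_next], target)
    } else {
      t_hi <- t_max
      target <- NA_real_
      cap <- n
      nc0 <- last_interval_censor_init(
        n_start = n, t_lo = t_lo, t_max = t_max, trisk1 = prep$trisk[1L],
        cens_so_far = sum(ncensor[seq_len(i - 1L)]),
        d_so_far = sum(d_hat), endpts = endpts, tot_events = tot_events)
    }
    if (t_hi <= t_lo) t_hi <- t_lo + 1e-9   # degenerate single-time interval
    fit <- fit_interval(pts$time[idx], pts$surv[idx], n_start = n,
                        t_lo = t_lo, t_hi = t_hi,
                        t_next = if (last) Inf else t_hi,
                        ncensor_init = nc0, cap = cap, target = target,
                        S_last_in = S_last, max_iter = max_iter)
    d_hat[idx] <- fit$d
    cens_hat[idx] <- fit$cens
    n_hat[idx] <- fit$n_at
    S_km[idx] <- fit$S_km
    ncensor[i] <- sum(fit$cens)
    if (any(fit$d > 0)) {
      event_rows[[i]] <- rep(pts$time[idx][fit$d > 0], fit$d[fit$d > 0])
    }
    if (length(fit$tcensor_used)) censor_rows[[i]] <- fit$tcensor_used
    n <- fit$n_end
    S_last <- fit$S_last_end
  }

  ev <- unlist(event_rows) %||% numeric(0)
  cn <- unlist(censor_rows) %||% numeric(0)
  ipd <- data.frame(
    time = c(ev, cn, rep(t_max, n)),
    status = c(rep(1L, length(ev)), rep(0L, length(cn) + n)),
    arm = arm
  )
  ipd <- ipd[order(ipd$time, -ipd$status), , drop = FALSE]
  rownames(ipd) <- NULL

  audit <- data.frame(
    interval = seq_len(I),
    lower = prep$lower, upper = prep$upper,
    trisk = prep$trisk, nrisk = prep$nrisk,
    nrisk_hat = n_hat[prep$lower],
    ncensor_hat = ncensor,
    events = vapply(seq_len(I),
                    function(i) sum(d_hat[prep$lower[i]:prep$upper[i]]),
                    numeric(1))
  )

  structure(list(
    ipd = ipd,
    estimates = data.frame(time = pts$time, surv = pts$surv,
                           n_hat = n_hat, d_hat = d_hat,
                           cens_hat = cens_hat, S_km = S_km),
    audit = audit,
    n_final = n,
    prep = prep,
    arm = arm,
    tot_events = tot_events,
    endpts = endpts
  ), class = "km_recon")
}

#' @export
print.km_recon <- function(x, ...) {
  cat("Reconstructed IPD for arm '", x$arm, "': ", nrow(x$ipd),
      " patients, ", sum(x$ipd$status), " events, ",
      sum(x$ipd$status == 0), " censored\n", sep = "")
  cat("Per-interval audit:\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
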