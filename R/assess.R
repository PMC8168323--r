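# Accuracy assessment: how well does the reconstructed IPD reproduce the
# digitized curve and the published number-at-risk table?

#' Accuracy summary of a reconstruction
#'
#' Evaluates the Kaplan-Meier curve of the reconstructed IPD at every
#' read-in (cleaned) coordinate time and summarizes the residuals against
#' the read-in survival probabilities: RMSE, mean and max absolute error,
#' and a two-sample Kolmogorov-Smirnov comparison of the read-in and
#' estimated survival values. When a risk table is available, the estimated
#' number at risk at each report time is tabulated against the published
#' count.
#'
#' Thresholds RMSE <= 0.05, mean absolute error <= 0.02 and max absolute
#' error <= 0.05 indicate that the digitized points are well captured; they
#' are a rule of thumb and are surfaced as flags/warnings, not errors.
#'
#' @param prep the \code{"km_prep"} the reconstruction was built from (or a
#'   \code{"km_recon"}, in which case \code{ipd} may be omitted).
#' @param ipd the reconstructed IPD (data frame or \code{"km_recon"}).
#' @param warn warn when a threshold is exceeded (default TRUE).
#' @return object of class \code{"km_accuracy"}: list with \code{rmse},
#'   \code{mean_abs_err}, \code{max_abs_err}, \code{ks_stat}, \code{ks_p},
#'   \code{pass} (named logical flags), \code{residuals} (per-coordinate
#'   table), and \code{nrisk_table} (NULL without a risk table).
#' @examples
#' sim <- simulate_km_arm(seed = 1)
#' prep <- preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk)
#' rec <- reconstruct_ipd(prep)
#' accuracy_summary(rec)
#' @export
accuracy_summary <- function(prep, ipd = NULL, warn = TRUE) {
  if (inherits(prep, "km_recon")) {
    rec <- prep
    prep <- rec$prep
    ipd <- ipd %||% rec$ipd
    est <- rec$estimates
    audit <- rec$audit
  } else {
    if (is.null(ipd)) stop_input("ipd required when prep is not a km_recon")
    est <- NULL
    audit <- NULL
  }
  if (inherits(ipd, "km_recon")) ipd <- ipd$ipd
  pts <- prep$points
  if (max(ipd$time) < pts$time[1L] || nrow(ipd) != prep$nrisk[1L])
    stop_input("IPD does not appear to be reconstructed from this curve")

  fit <- km_fit(ipd)
  S_hat <- surv_at(fit, pts$time)
  # a coordinate followed by another at the same time digitizes the top of a
  # vertical drop: its counterpart on the estimated curve is the value just
  # before the drop (left limit), not the post-drop step value
  top <- duplicated(pts$time, fromLast = TRUE)
  if (any(top)) {
    idx <- findInterval(pts$time[top], fit$time, left.open = TRUE)
    S_hat[top] <- c(1, fit$surv)[idx + 1L]
  }
  r <- S_hat - pts$surv
  rmse <- sqrt(mean(r^2))
  mean_abs <- mean(abs(r))
  max_abs <- max(abs(r))
  ks <- suppressWarnings(stats::ks.test(pts$surv, S_hat))

  nrisk_table <- NULL
  if (!is.null(audit) && length(prep$trisk) > 1L) {
    nrisk_table <- data.frame(trisk = audit$trisk,
                              reported = audit$nrisk,
                              estimated = audit$nrisk_hat,
                              error = audit$nrisk_hat - audit$nrisk)
  }

  pass <- c(rmse = rmse <= 0.05, mean_abs_err = mean_abs <= 0.02,
            max_abs_err = max_abs <= 0.05)
  if (warn && !all(pass))
    warning("reconstruction accuracy exceeds recommended threshold(s): ",
            paste(names(pass)[!pass], collapse = ", "),
            "; consider re-extracting the data points", call. = FALSE)

  structure(list(rmse = rmse, mean_abs_err = mean_abs, max_abs_err = max_abs,
                 ks_stat = unname(ks$statistic), ks_p = unname(ks$p.value),
                 pass = pass,
                 residuals = data.frame(time = pts$time, read_in = pts$surv,
                                        estimated = S_hat, residual = r),
                 nrisk_table = nrisk_table),
            class = "km_accuracy")
}

#' Number-at-risk recovery errors
#'
#' Per-report-time signed error (estimated minus reported number at risk)
#' and the mean absolute error across the report times.
#'
#' @param rec a \code{"km_recon"} object (or its \code{audit} table).
#' @return list with \code{table} (trisk, reported, estimated, error) and
#'   \code{mean_abs_err}.
#' @export
nrisk_recovery <- function(rec) {
  audit <- if (inherits(rec, "km_recon")) rec$audit else as.data.frame(rec)
  err <- audit$nrisk_hat - audit$nrisk
  list(table = data.frame(trisk = audit$trisk, reported = audit$nrisk,
                          estimated = audit$nrisk_hat, error = err),
       mean_abs_err = mean(abs(err)))
}

#' @export
summary.km_recon <- function(object, ...) {
  accuracy_summary(object, warn = FALSE)
}

#' @export
print.km_accuracy <- function(x, ...) {
  cat(sprintf(
    "Accuracy of reconstruction:\n  RMSE           %.4f (threshold 0.05)\n  mean |error|   %.4f (threshold 0.02)\n  max |error|    %.4f (threshold 0.05)\n  K-S statistic  %.4f (p = %.3f)\n",
    x$rmse, x$mean_abs_err, x$max_abs_err, x$ks_stat, x$ks_p))
  if (!all(x$pass))
    cat("  ! threshold exceeded:", paste(names(x$pass)[!x$pass],
                                         collapse = ", "), "\n")
  if (!is.null(x$nrisk_table)) {
    cat("Number at risk, reported vs estimated:\n")
    print(x$nrisk_table, row.names = FALSE)
  }
  invisible(x)
}

#' Diagnostic plots for a reconstruction
#'
#' Draws up to three base-graphics panels: the read-in coordinates overlaid
#' with the Kaplan-Meier curve of the reconstructed IPD, the reported versus
#' estimated number at risk, and the per-coordinate survival residuals.
#'
#' @param x a \code{"km_recon"} object.
#' @param which subset of \code{1:3} selecting panels.
#' @param ... passed to \code{plot}.
#' @export
plot.km_recon <- function(x, which = 1:3, ...) {
  acc <- accuracy_summary(x, warn = FALSE)
  if (is.null(acc$nrisk_table)) which <- setdiff(which, 2L)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  fit <- km_fit(x$ipd)
  if (1L %in% which) {
    plot(x$prep$points$time, x$prep$points$surv, pch = 20, cex = 0.5,
         xlab = "Time", ylab = "Survival probability", ylim = c(0, 1),
         main = "Read-in vs reconstructed", ...)
    graphics::lines(c(0, rep(fit$time, each = 2)),
                    c(1, 1, rep(fit$surv[-length(fit$surv)], each = 2),
                      fit$surv[length(fit$surv)]), col = 2)
  }
  if (2L %in% which) {
    nt <- acc$nrisk_table
    plot(nt$trisk, nt$reported, type = "b", pch = 1,
         xlab = "Time", ylab = "Number at risk",
         main = "Number at risk", ...)
    graphics::points(nt$trisk, nt$estimated, pch = 4, col = 2)
    graphics::legend("topright", c("reported", "estimated"),
                     pch = c(1, 4), col = c(1, 2), bty = "n")
  }
  if (3L %in% which) {
    plot(acc$residuals$time, acc$residuals$residual, pch = 20, cex = 0.5,
         xlab = "Time", ylab = "Estimated - read-in",
         main = "Survival residuals", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
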