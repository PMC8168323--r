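#' Sort, rescale and anchor digitized Kaplan-Meier coordinates
#'
#' Sorts the digitized coordinates by time (stable, so points digitized
#' top-of-drop before bottom-of-drop keep that order at tied times), detects
#' percent-scaled survival axes, and prepends an anchor point
#' \code{(t0, 1)} when the digitized curve does not start at full survival.
#'
#' @param points data frame (or matrix) with numeric columns \code{time} and
#'   \code{surv}; extra columns are dropped.
#' @param t0 time origin of the curve, normally the first risk-table time.
#'   Used for the anchor point.
#' @return data frame with columns \code{time}, \code{surv}, carrying
#'   attribute \code{scale_factor} (1 for fractions, 100 when a percent axis
#'   was detected and divided out).
#' @details A curve whose maximum survival value exceeds 1.5 is taken to be
#'   reported in percent and divided by 100: survival fractions never exceed
#'   1, while percent axes start well above that. An anchor \code{(t0, 1)} is
#'   prepended when the earliest digitized survival is below 1 and no point
#'   sits at \code{t0}, so the first product-limit factor is well defined.
#' @export
normalize_points <- function(points, t0 = 0) {
  pts <- as_points(points)
  if (nrow(pts) < 2L)
    stop_input("need at least 2 digitized points, got ", nrow(pts))
  if (any(!is.finite(pts$time)) || any(!is.finite(pts$surv)))
    stop_input("non-finite time or survival values in digitized points")
  if (any(pts$time < 0))
    stop_input("negative time values in digitized points")
  if (any(pts$surv < 0))
    stop_input("negative survival values in digitized points")

  scale_factor <- 1
  if (max(pts$surv) > 1.5) {
    pts$surv <- pts$surv / 100
    scale_factor <- 100
  }
  if (max(pts$surv) > 1 + 1e-8)
    pts$surv <- pmin(pts$surv, 1)

  pts <- pts[order(pts$time), , drop = FALSE]  # order() is a stable sort
  rownames(pts) <- NULL

  if (pts$surv[1L] < 1 && !any(pts$time == t0)) {
    pts <- rbind(data.frame(time = t0, surv = 1), pts)
  }
  attr(pts, "scale_factor") <- scale_factor
  pts
}

#' Remove digitization blunders with Tukey's fence
#'
#' Flags outlying points among digitized Kaplan-Meier coordinates using
#' Tukey's fence on the successive survival increments
#' \eqn{S_k - S_{k-1}}. Genuine curve geometry produces increments that are
#' zero (horizontal runs) or modest drops; gross extraction errors show up as
#' anomalous jumps and are removed.
#'
#' @param points sorted coordinate data frame (\code{time}, \code{surv}).
#' @param k fence multiplier; the default 3 is deliberately loose so that
#'   genuine data points are not discarded.
#' @return the filtered points; attribute \code{removed} holds the (input)
#'   indices of dropped points.
#' @details The fence is \eqn{[Q_1 - k\,IQR,\; Q_3 + k\,IQR]} computed on the
#'   \eqn{N-1} successive increments; the point terminating an out-of-fence
#'   increment is removed. Curves with fewer than 4 points pass unchanged.
#' @export
fence_outliers <- function(points, k = 3) {
  pts <- as_points(points)
  if (k <= 0) stop_input("fence multiplier k must be positive")
  if (nrow(pts) < 4L) {
    attr(pts, "removed") <- integer(0)
    return(pts)
  }
  inc <- diff(pts$surv)
  qs <- stats::quantile(inc, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2L] - qs[1L]
  # small absolute slack so a degenerate (zero-IQR) fence does not flag
  # increments that differ only by floating-point error
  tol <- 1e-8
  lo <- qs[1L] - k * iqr - tol
  hi <- qs[2L] + k * iqr + tol
  bad <- which(inc < lo | inc > hi) + 1L
  out <- pts[setdiff(seq_len(nrow(pts)), bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale_factor") <- attr(pts, "scale_factor")
  attr(out, "removed") <- bad
  out
}

#' Force monotone non-increasing survival
#'
#' Replaces the survival column by its running minimum so that survival never
#' increases with time. No points are deleted and times are untouched;
#' this repairs small upward digitization wobble left after outlier removal.
#'
#' @param points sorted coordinate data frame (\code{time}, \code{surv}).
#' @return points with \code{surv} replaced by \code{cummin(surv)}.
#' @export
force_monotone <- function(points) {
  pts <- as_points(points)
  sf <- attr(points, "scale_factor")
  pts$surv <- cummin(pts$surv)
  attr(pts, "scale_factor") <- sf
  pts
}

#' Reduce every vertical drop to its top and bottom point
#'
#' On a digitized Kaplan-Meier curve several points may share one time value
#' (a vertical drop). Keeping them all makes the event count of the drop
#' round once per point, which can round a true drop down to zero events.
#' Step control retains only the first (highest survival) and last (lowest
#' survival) point of each run of tied times, so each drop's event count is
#' computed and rounded exactly once.
#'
#' @param points sorted, monotone coordinate data frame.
#' @return points with interior points of each vertical run removed.
#' @export
step_control <- function(points) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  first <- !duplicated(pts$time)
  last <- !duplicated(pts$time, fromLast = TRUE)
  out <- pts[first | last, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale_factor") <- attr(pts, "scale_factor")
  out
}

#' Partition cleaned coordinates into risk-table intervals
#'
#' Assigns each cleaned coordinate to the reporting interval of the published
#' number-at-risk table: interval \eqn{i} covers times in
#' \eqn{[trisk_i, trisk_{i+1})} and the last interval is closed on the right
#' at the last coordinate. Without a risk table a single interval spanning
#' all points is created from the supplied total sample size.
#'
#' @param points cleaned coordinate data frame.
#' @param trisk strictly increasing risk-report times, or NULL.
#' @param nrisk non-increasing positive at-risk counts, same length as
#'   \code{trisk}, or NULL.
#' @param total_n total number of patients; required when no risk table is
#'   given, otherwise defaults to \code{nrisk[1]}.
#' @return an object of class \code{"km_prep"}: list with elements
#'   \code{points}, \code{trisk}, \code{nrisk}, \code{lower}, \code{upper}
#'   (per-interval first/last point index), \code{total_n},
#'   \code{scale_factor}, and \code{riskmat} (per-interval audit table).
#' @details Intervals that would contain no digitized point are merged into
#'   their predecessor with a warning (their \code{trisk}/\code{nrisk}
#'   entries are kept in \code{dropped_risk} for reporting). Points earlier
#'   than \code{trisk[1]} are rejected.
#' @export
partition_intervals <- function(points, trisk = NULL, nrisk = NULL,
                                total_n = NULL) {
  pts <- as_points(points)
  n <- nrow(pts)
  dropped <- NULL

  if (is.null(trisk) != is.null(nrisk))
    stop_input("trisk and nrisk must be supplied together")

  if (is.null(trisk)) {
    if (is.null(total_n))
      stop_input("either a risk table (trisk, nrisk) or total_n is required")
    trisk_use <- pts$time[1L]
    nrisk_use <- as.integer(total_n)
    lower <- 1L
    upper <- n
  } else {
    check_risk_table(trisk, nrisk)
    if (any(pts$time < trisk[1L]))
      stop_input("digitized times precede the first risk time trisk[1]")
    total_n <- total_n %||% nrisk[1L]
    # half-open windows [trisk_i, trisk_{i+1}), last interval right-closed
    idx <- findInterval(pts$time, trisk)
    keep <- sort(unique(idx))
    if (length(keep) < length(trisk)) {
      empty <- setdiff(seq_along(trisk), keep)
      warning("risk-table interval(s) ", paste(empty, collapse = ", "),
              " contain no digitized points; merged into predecessor",
              call. = FALSE)
      dropped <- data.frame(interval = empty, trisk = trisk[empty],
                            nrisk = nrisk[empty])
      # points in a merged window already map to the preceding retained entry
    }
    trisk_use <- trisk[keep]
    nrisk_use <- as.integer(nrisk[keep])
    idx <- match(idx, keep)
    lower <- vapply(seq_along(keep), function(i) min(which(idx == i)), 1L)
    upper <- vapply(seq_along(keep), function(i) max(which(idx == i)), 1L)
    if (any(lower[-1L] != upper[-length(upper)] + 1L))
      stop("internal error: interval indices are not contiguous")
  }

  prep <- structure(list(
    points = pts,
    trisk = trisk_use,
    nrisk = nrisk_use,
    lower = as.integer(lower),
    upper = as.integer(upper),
    total_n = as.integer(total_n),
    scale_factor = attr(pts, "scale_factor") %||% 1,
    dropped_risk = dropped,
    riskmat = data.frame(interval = seq_along(trisk_use),
                         trisk = trisk_use, nrisk = nrisk_use,
                         lower = as.integer(lower), upper = as.integer(upper))
  ), class = "km_prep")
  prep
}

#' Preprocess raw digitized Kaplan-Meier coordinates
#'
#' Complete preprocessing pipeline: sort/rescale/anchor, remove outliers with
#' Tukey's fence, force monotonicity, apply step control, and partition the
#' points into the risk-table intervals. The result feeds directly into
#' \code{\link{reconstruct_ipd}}.
#'
#' @param points raw digitized coordinates: data frame/matrix with time in
#'   the first column and survival (fraction or percent) in the second.
#' @param trisk,nrisk published number-at-risk table (times and counts), or
#'   both NULL when unavailable.
#' @param total_n total number of patients; required if no risk table.
#' @param fence_k Tukey fence multiplier (default 3).
#' @return object of class \code{"km_prep"}; see
#'   \code{\link{partition_intervals}}.
#' @examples
#' sim <- simulate_km_arm(seed = 1)
#' prep <- preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk)
#' prep
#' @export
preprocess_curve <- function(points, trisk = NULL, nrisk = NULL,
                             total_n = NULL, fence_k = 3) {
  t0 <- if (!is.null(trisk)) trisk[1L] else 0
  pts <- normalize_points(points, t0 = t0)
  pts <- fence_outliers(pts, k = fence_k)
  removed <- attr(pts, "removed")
  pts <- force_monotone(pts)
  pts <- step_control(pts)
  prep <- partition_intervals(pts, trisk = trisk, nrisk = nrisk,
                              total_n = total_n)
  prep$removed <- removed
  prep
}

#' @export
print.km_prep <- function(x, ...) {
  cat("Preprocessed K-M curve: ", nrow(x$points), " points, ",
      length(x$trisk), " interval(s), total n = ", x$total_n, "\n", sep = "")
  if (length(x$removed)) {
    cat("Outliers removed at input indices:",
        paste(x$removed, collapse = ", "), "\n")
  }
  print(x$riskmat, row.names = FALSE)
  invisible(x)
}

# ---- internal -------------------------------------------------------------

as_points <- function(points) {
  if (inherits(points, "km_prep")) return(points$points)
  pts <- as.data.frame(points)
  if (ncol(pts) < 2L)
    stop_input("coordinate table needs two columns (time, survival)")
  pts <- pts[, 1:2]
  names(pts) <- c("time", "surv")
  pts$time <- as.numeric(pts$time)
  pts$surv <- as.numeric(pts$surv)
  if (anyNA(pts$time) || anyNA(pts$surv))
    stop_input("coordinate table contains missing or non-numeric values")
  rownames(pts) <- NULL
  pts
}

check_risk_table <- function(trisk, nrisk) {
  if (length(trisk) != length(nrisk))
    stop_input("trisk and nrisk differ in length")
  if (length(trisk) < 1L) stop_input("empty risk table")
  if (any(diff(trisk) <= 0))
    stop_input("trisk must be strictly increasing")
  if (any(diff(nrisk) > 0))
    stop_input("nrisk must be non-increasing")
  if (any(nrisk <= 0) || any(nrisk != round(nrisk)))
    stop_input("nrisk must be positive integers")
  invisible(TRUE)
}
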