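# File input/output and axis calibration for digitized pixel coordinates.

#' Read digitized coordinates from a delimited file
#'
#' Tolerant CSV/TSV ingestion of digitized Kaplan-Meier coordinates. The
#' delimiter (comma or tab) is sniffed, a header row is detected
#' automatically, and three layouts are accepted: two columns
#' (time, survival), three columns (time, survival, arm label), or four
#' columns (two side-by-side time/survival pairs, one per arm).
#'
#' @param path file path.
#' @param sep delimiter; NULL (default) to sniff.
#' @return for a single-arm layout, a coordinate data frame; for two-arm
#'   layouts, a named list of two coordinate data frames.
#' @export
read_points <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input("empty coordinate file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[1:2]))))
  raw <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                           header = has_header, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  check_numeric_cols <- function(cols, offset = 0L) {
    for (j in cols) {
      v <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(trimws(raw[[j]])))
      if (length(bad))
        stop_input("non-numeric value in column ", j, " at line ",
                   bad[1L] + has_header, " of ", path)
      if (anyNA(v))
        stop_input("missing value in column ", j, " at line ",
                   which(is.na(v))[1L] + has_header, " of ", path)
      raw[[j]] <<- v
    }
  }
  if (ncol(raw) == 2L) {
    check_numeric_cols(1:2)
    data.frame(time = raw[[1L]], surv = raw[[2L]])
  } else if (ncol(raw) == 3L) {
    check_numeric_cols(1:2)
    split_arms <- split(raw, raw[[3L]])
    lapply(split_arms, function(d)
      data.frame(time = d[[1L]], surv = d[[2L]], row.names = NULL))
  } else if (ncol(raw) == 4L) {
    check_numeric_cols(1:4)
    out <- list(
      arm1 = data.frame(time = raw[[1L]], surv = raw[[2L]]),
      arm2 = data.frame(time = raw[[3L]], surv = raw[[4L]])
    )
    lapply(out, function(d) d[stats::complete.cases(d), , drop = FALSE])
  } else {
    stop_input("expected 2, 3 or 4 columns in ", path, ", found ", ncol(raw))
  }
}

#' Write reconstructed IPD to CSV
#'
#' @param ipd IPD table or \code{"km_recon"} object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  if (inherits(ipd, "km_recon")) ipd <- ipd$ipd
  utils::write.csv(ipd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a combined reconstruction report
#'
#' Serializes the reconstruction audit, accuracy assessment and (optionally)
#' a secondary survival analysis into a canonical JSON report, plus a
#' human-readable text rendering next to it.
#'
#' @param rec a \code{"km_recon"} object.
#' @param path output path for the JSON report (a \code{.txt} twin is
#'   written alongside).
#' @param report optional \code{"survreport"} to include.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(rec, path, report = NULL) {
  stopifnot(inherits(rec, "km_recon"))
  acc <- accuracy_summary(rec, warn = FALSE)
  payload <- list(
    schema = "survrecon-report/1",
    arm = rec$arm,
    n_patients = nrow(rec$ipd),
    n_events = sum(rec$ipd$status),
    audit = rec$audit,
    accuracy = list(rmse = acc$rmse, mean_abs_err = acc$mean_abs_err,
                    max_abs_err = acc$max_abs_err, ks_stat = acc$ks_stat,
                    ks_p = acc$ks_p, pass = as.list(acc$pass)),
    nrisk_table = acc$nrisk_table
  )
  if (!is.null(report)) {
    payload$survreport <- list(
      interval = report$interval,
      landmark = lapply(report$per_arm, `[[`, "landmark"),
      quantiles = lapply(report$per_arm, `[[`, "quantiles"),
      logrank = report$logrank,
      hazard_ratio = report$hazard_ratio
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(rec); print(acc)
  if (!is.null(report)) print(report)
  invisible(path)
}

#' Map pixel coordinates to data units
#'
#' Affine axis calibration for digitized pixel coordinates: given the pixel
#' positions of two reference points per axis and their axis labels in data
#' units, maps every clicked pixel to (time, survival). The y-axis flip
#' between screen coordinates (down) and data coordinates (up) is handled by
#' the affine map itself.
#'
#' @param cal list with \code{px} (pixel x of the left and right x-axis
#'   reference points), \code{x} (their labels), \code{py} (pixel y of the
#'   lower and upper y-axis reference points), \code{y} (their labels).
#' @param pixel_points two-column matrix/data frame of clicked pixels
#'   (pixel x, pixel y).
#' @return coordinate data frame (\code{time}, \code{surv}).
#' @export
calibrate_pixels <- function(cal, pixel_points) {
  need <- c("px", "x", "py", "y")
  if (!all(need %in% names(cal)))
    stop_input("calibration needs elements px, x, py, y")
  if (cal$px[1L] == cal$px[2L] || cal$py[1L] == cal$py[2L])
    stop_input("coincident reference pixels; cannot calibrate axis")
  pp <- as.data.frame(pixel_points)
  ax <- function(p, ref_p, ref_v)
    ref_v[1L] + (p - ref_p[1L]) * diff(ref_v) / diff(ref_p)
  data.frame(time = ax(pp[[1L]], cal$px, cal$x),
             surv = ax(pp[[2L]], cal$py, cal$y))
}
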