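#' Line-scan series
#'
#' Container for a space-time image: rows are sequential line-scans in time,
#' columns are positions along the scan path. Moving particles trace oblique
#' streaks whose slope encodes their speed.
#'
#' @param data Numeric matrix, T rows (time) by L columns (space), T >= 2,
#'   L >= 4, all values finite.
#' @param calibration A \code{\link{scan_calibration}}.
#' @param background_removed Has the per-column temporal mean been subtracted?
#' @param roi_origin_px 0-based column offset of this series within the
#'   original full scan (updated by \code{\link{extract_roi}}).
#'
#' @return An object of class \code{line_scan_series}.
#' @export
line_scan_series <- function(data, calibration, background_removed = FALSE,
                             roi_origin_px = 0L) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric matrix (rows = time, columns = space)")
  }
  if (nrow(data) < 2L) stop("need at least 2 line-scans (rows)")
  if (ncol(data) < 4L) stop("need at least 4 spatial columns")
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]))
  }
  if (!inherits(calibration, "scan_calibration")) {
    stop("calibration must be a scan_calibration object")
  }
  structure(
    list(data = data,
         calibration = calibration,
         background_removed = isTRUE(background_removed),
         roi_origin_px = as.integer(roi_origin_px)),
    class = "line_scan_series"
  )
}

#' @export
print.line_scan_series <- function(x, ...) {
  cat(sprintf(
    "<line_scan_series> %d scans x %d px (%.4g um/px, %.6g Hz)%s, origin %d px\n",
    nrow(x$data), ncol(x$data), x$calibration$pixel_size_um,
    x$calibration$line_rate_hz,
    if (x$background_removed) ", background-removed" else "",
    x$roi_origin_px))
  invisible(x)
}

#' @export
dim.line_scan_series <- function(x) dim(x$data)

#' Velocity trace
#'
#' Time series of velocities estimated from a line-scan series, one point per
#' (possibly frame-averaged) correlogram. Velocity is signed along the scan
#' axis: positive means motion toward increasing column index.
#'
#' @param time_s Time of each point, seconds.
#' @param velocity_mm_s Signed velocity, mm/s. \code{NA} for fit failures.
#' @param shift_px Fitted sub-pixel displacement per delayed pair.
#' @param peak_quality Fit-quality score in \code{[0, 1]}.
#' @param outlier_flag Logical: flagged as erroneous (fit failure or running
#'   window outlier).
#' @param calibration Optional \code{\link{scan_calibration}} attached as an
#'   attribute.
#' @param delay_steps Optional delay (scan intervals) attached as an attribute.
#'
#' @return A data frame of class \code{velocity_trace}.
#' @export
velocity_trace <- function(time_s, velocity_mm_s,
                           shift_px = rep(NA_real_, length(time_s)),
                           peak_quality = rep(1, length(time_s)),
                           outlier_flag = rep(FALSE, length(time_s)),
                           calibration = NULL, delay_steps = NA_integer_) {
  n <- length(time_s)
  if (length(velocity_mm_s) != n || length(shift_px) != n ||
      length(peak_quality) != n || length(outlier_flag) != n) {
    stop("all velocity_trace columns must share one length")
  }
  out <- data.frame(time_s = as.numeric(time_s),
                    velocity_mm_s = as.numeric(velocity_mm_s),
                    shift_px = as.numeric(shift_px),
                    peak_quality = as.numeric(peak_quality),
                    outlier_flag = as.logical(outlier_flag))
  class(out) <- c("velocity_trace", "data.frame")
  attr(out, "calibration") <- calibration
  attr(out, "delay_steps") <- delay_steps
  out
}

#' @export
print.velocity_trace <- function(x, ...) {
  ok <- !x$outlier_flag & is.finite(x$velocity_mm_s)
  cat(sprintf("<velocity_trace> %d points over %.3f s, %d flagged\n",
              nrow(x), diff(range(x$time_s)), sum(x$outlier_flag)))
  if (any(ok)) {
    cat(sprintf("  velocity (unflagged): mean %.3f, range [%.3f, %.3f] mm/s\n",
                mean(x$velocity_mm_s[ok]), min(x$velocity_mm_s[ok]),
                max(x$velocity_mm_s[ok])))
  }
  invisible(x)
}
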