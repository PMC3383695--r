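#' Scan calibration
#'
#' Records the physical meaning of a space-time image: how many micrometers
#' one column spans and how many line-scans are acquired per second. Every
#' pixel-shift-to-velocity conversion in the package goes through this record.
#'
#' @param pixel_size_um Length of one pixel along the scan path, in
#'   micrometers per pixel. Must be positive. Two-photon systems used for
#'   cortical velocimetry typically resolve ~0.4-0.5 um per pixel.
#' @param line_rate_hz Number of line-scans acquired per second (Hz). Must be
#'   positive. The reference acquisition rate throughout the package is
#'   2600 Hz.
#' @param scan_direction Either \code{"unidirectional"} (every scan sweeps the
#'   same way) or \code{"bidirectional"} (alternating sweeps; see the
#'   \code{deinterlace} argument of \code{\link{read_spacetime}}).
#'
#' @return An object of class \code{scan_calibration}.
#' @examples
#' scan_calibration(pixel_size_um = 0.5, line_rate_hz = 2600)
#' @export
scan_calibration <- function(pixel_size_um, line_rate_hz,
                             scan_direction = c("unidirectional", "bidirectional")) {
  scan_direction <- match.arg(scan_direction)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive finite number")
  }
  if (!is.numeric(line_rate_hz) || length(line_rate_hz) != 1L ||
      !is.finite(line_rate_hz) || line_rate_hz <= 0) {
    stop("line_rate_hz must be a single positive finite number")
  }
  structure(
    list(pixel_size_um = as.numeric(pixel_size_um),
         line_rate_hz = as.numeric(line_rate_hz),
         scan_direction = scan_direction),
    class = "scan_calibration"
  )
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat(sprintf("<scan_calibration> %.4g um/px, %.6g lines/s, %s\n",
              x$pixel_size_um, x$line_rate_hz, x$scan_direction))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles every tunable parameter of the velocimetry pipeline. All column
#' indices are 0-based and ranges are half-open, so a region of interest
#' \code{[roi_start_px, roi_end_px)} contains \code{roi_end_px - roi_start_px}
#' columns.
#'
#' @param roi_start_px,roi_end_px Column range to analyze (0-based, half-open).
#'   \code{roi_end_px = NA} means "to the last column".
#' @param delay_steps Number of scan intervals between the cross-correlated
#'   pair. \code{NA} requests automatic selection via
#'   \code{\link{select_delay}}: fast flows need a delay of one scan, slow
#'   capillary flows need the Nth-neighbour pairing so the displacement grows
#'   beyond pixel resolution.
#' @param frame_average_window Number of consecutive correlograms averaged into
#'   one velocity point. \code{NA} derives it from
#'   \code{velocity_points_per_second} as \code{floor(line_rate / points)}.
#' @param velocity_points_per_second Desired temporal density of the velocity
#'   trace. The native resolution equals the line rate (one point per scan
#'   pair); 100 points/s is a practical reduced-resolution mode.
#' @param outlier_threshold_sd Threshold \code{k}: a point is flagged when it
#'   deviates from the running windowed mean by more than \code{k} running
#'   standard deviations.
#' @param outlier_window Odd width (in points) of the running window used for
#'   outlier flagging.
#' @param median_filter_width Odd width (>= 3) of an optional running median
#'   applied to the final trace, or \code{NULL} for none.
#' @param phase_exponent Exponent \code{alpha} of the symmetric phase-weighted
#'   filter, in \code{[0, 1]}. 1 is pure phase-only filtering; 0 is plain
#'   cross-correlation.
#' @param fit_halfwidth_px Half-width \code{w} of the Gaussian fit window:
#'   \code{2w + 1} correlogram samples centred on the peak are fitted.
#' @param edge_guard_px Number of columns zeroed at each end of the
#'   \emph{reference} row before correlation (the delayed row keeps its full
#'   support). Particles clipped by the window boundary are otherwise
#'   anchored at the same pixel in both rows and masquerade as a zero-lag
#'   correlation peak; guarding the reference removes the shared anchor, at
#'   the cost of a slightly shorter effective window. \code{NA} (default)
#'   chooses \code{ceiling(7 um / pixel_size)} - the largest red-cell-scale
#'   particle - capped at a sixth of the window; 0 disables the guard.
#' @param symmetric_pairing If \code{TRUE} (default) each correlogram is the
#'   average of the forward correlogram and the lag-mirrored correlogram with
#'   the roles of reference and delayed scan exchanged. Exchanging roles
#'   negates the true displacement peak but leaves window-anchored artifacts
#'   in place, so the average cancels odd-order (direction-dependent) bias -
#'   the 1-D analogue of central-difference interrogation in planar PIV. Costs
#'   a second correlation pass.
#' @param min_peak_psr Minimum peak-to-sidelobe ratio: correlogram rows whose
#'   global maximum does not exceed the off-peak mean by at least this many
#'   off-peak standard deviations are flagged as detection failures (no
#'   reliable displacement peak). 0 disables. The default 4 is a conventional
#'   detectability floor for correlation peaks.
#' @param min_shift_px Pilot-pass displacement floor used by
#'   \code{\link{select_delay}}; the delay is doubled until the median absolute
#'   shift reaches this many pixels.
#' @param max_delay_steps Upper bound for automatic delay selection.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(roi_start_px = 0L,
                            roi_end_px = NA_integer_,
                            delay_steps = NA_integer_,
                            frame_average_window = NA_integer_,
                            velocity_points_per_second = 100,
                            outlier_threshold_sd = 3,
                            outlier_window = 101L,
                            median_filter_width = NULL,
                            phase_exponent = 1,
                            fit_halfwidth_px = 4L,
                            edge_guard_px = NA_integer_,
                            symmetric_pairing = TRUE,
                            min_peak_psr = 4,
                            min_shift_px = 3,
                            max_delay_steps = 32L,
                            seed = NULL) {
  roi_start_px <- as.integer(roi_start_px)
  if (is.na(roi_start_px) || roi_start_px < 0L) {
    stop("roi_start_px must be a non-negative integer")
  }
  if (!is.na(roi_end_px)) {
    roi_end_px <- as.integer(roi_end_px)
    if (roi_end_px <= roi_start_px) {
      stop("roi_end_px must exceed roi_start_px (half-open column range)")
    }
  }
  if (!is.na(delay_steps)) {
    delay_steps <- as.integer(delay_steps)
    if (delay_steps < 1L) stop("delay_steps must be >= 1")
  }
  if (!is.na(frame_average_window)) {
    frame_average_window <- as.integer(frame_average_window)
    if (frame_average_window < 1L) stop("frame_average_window must be >= 1")
  }
  if (!is.numeric(velocity_points_per_second) || velocity_points_per_second <= 0) {
    stop("velocity_points_per_second must be > 0")
  }
  if (!is.numeric(outlier_threshold_sd) || outlier_threshold_sd <= 0) {
    stop("outlier_threshold_sd must be > 0")
  }
  outlier_window <- as.integer(outlier_window)
  if (outlier_window < 3L || outlier_window %% 2L == 0L) {
    stop("outlier_window must be an odd integer >= 3")
  }
  if (!is.null(median_filter_width)) {
    median_filter_width <- as.integer(median_filter_width)
    if (median_filter_width < 3L || median_filter_width %% 2L == 0L) {
      stop("median_filter_width must be an odd integer >= 3 (or NULL)")
    }
  }
  if (!is.numeric(phase_exponent) || phase_exponent < 0 || phase_exponent > 1) {
    stop("phase_exponent must lie in [0, 1]")
  }
  fit_halfwidth_px <- as.integer(fit_halfwidth_px)
  if (fit_halfwidth_px < 1L) stop("fit_halfwidth_px must be >= 1")
  if (!is.na(edge_guard_px)) {
    edge_guard_px <- as.integer(edge_guard_px)
    if (edge_guard_px < 0L) stop("edge_guard_px must be >= 0")
  }
  if (!is.numeric(min_shift_px) || min_shift_px <= 0) {
    stop("min_shift_px must be > 0")
  }
  if (!is.numeric(min_peak_psr) || min_peak_psr < 0) {
    stop("min_peak_psr must be >= 0")
  }
  max_delay_steps <- as.integer(max_delay_steps)
  if (max_delay_steps < 1L) stop("max_delay_steps must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(roi_start_px = roi_start_px,
         roi_end_px = roi_end_px,
         delay_steps = delay_steps,
         frame_average_window = frame_average_window,
         velocity_points_per_second = as.numeric(velocity_points_per_second),
         outlier_threshold_sd = as.numeric(outlier_threshold_sd),
         outlier_window = outlier_window,
         median_filter_width = median_filter_width,
         phase_exponent = as.numeric(phase_exponent),
         fit_halfwidth_px = fit_halfwidth_px,
         edge_guard_px = edge_guard_px,
         symmetric_pairing = isTRUE(symmetric_pairing),
         min_peak_psr = as.numeric(min_peak_psr),
         min_shift_px = as.numeric(min_shift_px),
         max_delay_steps = max_delay_steps,
         seed = seed),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
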