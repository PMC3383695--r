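#' Flag erroneous velocity points with a running windowed threshold
#'
#' Erroneous correlation fits tend to produce catastrophically high or low
#' velocities. Point i is flagged when it deviates from the mean of its
#' centred window by more than \code{threshold_sd} window standard
#' deviations. The running mean and sd exclude the candidate point itself
#' (leave-one-out), so one huge spike cannot mask itself by inflating its own
#' window sd. Windows shrink at the trace edges (no padding). \code{NA}
#' velocities (fit failures) stay flagged and are excluded from every window.
#'
#' @param trace A \code{\link{velocity_trace}}.
#' @param threshold_sd Threshold \code{k > 0}; a non-finite \code{k} flags
#'   nothing. When a window's sd is exactly 0, any non-zero deviation flags.
#' @param window Odd window width, \code{3 <= window <= nrow(trace)}.
#' @return The trace with \code{outlier_flag} updated (existing flags are
#'   kept).
#' @export
flag_outliers <- function(trace, threshold_sd, window) {
  stopifnot(inherits(trace, "velocity_trace"))
  n <- nrow(trace)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window > n || window %% 2L == 0L) {
    stop(sprintf("window must be an odd integer in [3, %d]", n))
  }
  v <- trace$velocity_mm_s
  usable <- is.finite(v)
  if (!is.finite(threshold_sd)) {
    trace$outlier_flag <- trace$outlier_flag | !usable
    return(trace)
  }
  h <- (window - 1L) %/% 2L
  vz <- ifelse(usable, v, 0)
  cs <- cumsum(c(0, vz))
  cs2 <- cumsum(c(0, vz^2))
  cn <- cumsum(c(0, as.numeric(usable)))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  S <- cs[hi + 1L] - cs[lo]
  Q <- cs2[hi + 1L] - cs2[lo]
  m <- cn[hi + 1L] - cn[lo]
  # leave-one-out: drop point i from its own window
  S <- S - ifelse(usable, v, 0)
  Q <- Q - ifelse(usable, v^2, 0)
  m <- m - as.numeric(usable)
  flag <- rep(FALSE, n)
  ok <- usable & m >= 2
  mu <- S[ok] / m[ok]
  varr <- pmax((Q[ok] - m[ok] * mu^2) / (m[ok] - 1), 0)
  dev <- abs(v[ok] - mu)
  thr <- threshold_sd * sqrt(varr)
  flag[ok] <- dev > thr | (thr == 0 & dev > 0)
  trace$outlier_flag <- trace$outlier_flag | flag | !usable
  trace
}

#' Running median filter for a velocity trace
#'
#' Replaces each velocity by the median of its centred window; near the trace
#' edges the window shrinks symmetrically (the point stays centred), so edge
#' points pass through unchanged rather than being averaged into a lopsided
#' window. The quality scores and outlier flags are preserved;
#' \code{shift_px} is recomputed from the filtered velocity when the trace
#' carries its calibration, keeping the shift/velocity relation consistent.
#'
#' @param trace A \code{\link{velocity_trace}}.
#' @param width Odd window width >= 3.
#' @return The filtered trace.
#' @export
median_filter_trace <- function(trace, width) {
  stopifnot(inherits(trace, "velocity_trace"))
  width <- as.integer(width)
  if (is.na(width) || width < 3L || width %% 2L == 0L) {
    stop("width must be an odd integer >= 3")
  }
  n <- nrow(trace)
  if (width > n) stop(sprintf("width (%d) exceeds trace length (%d)", width, n))
  h <- (width - 1L) %/% 2L
  v <- trace$velocity_mm_s
  out <- vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)  # symmetric shrink at the edges
    w <- v[(i - hi):(i + hi)]
    w <- w[is.finite(w)]
    if (length(w)) stats::median(w) else NA_real_
  }, 0)
  trace$velocity_mm_s <- out
  cal <- attr(trace, "calibration")
  N <- attr(trace, "delay_steps")
  if (!is.null(cal) && !is.na(N)) {
    trace$shift_px <- out * 1000 * N / (cal$pixel_size_um * cal$line_rate_hz)
  }
  trace
}

#' Summarize a velocity trace
#'
#' @param trace A \code{\link{velocity_trace}}.
#' @param exclude_outliers Drop flagged points before computing statistics?
#' @return An object of class \code{trace_summary}: \code{mean_mm_s},
#'   \code{peak_mm_s}, \code{trough_mm_s}, \code{pulsatility}
#'   (\code{(peak - trough) / mean}, the standard heartbeat-modulation
#'   index), \code{n_points} (points used), \code{n_outliers}.
#' @export
summarize_trace <- function(trace, exclude_outliers = TRUE) {
  stopifnot(inherits(trace, "velocity_trace"))
  keep <- is.finite(trace$velocity_mm_s)
  if (exclude_outliers) keep <- keep & !trace$outlier_flag
  v <- trace$velocity_mm_s[keep]
  if (!length(v)) stop("no usable points remain after outlier exclusion")
  m <- mean(v)
  structure(
    list(mean_mm_s = m,
         peak_mm_s = max(v),
         trough_mm_s = min(v),
         pulsatility = if (m != 0) (max(v) - min(v)) / m else NA_real_,
         n_points = length(v),
         n_outliers = sum(trace$outlier_flag)),
    class = "trace_summary"
  )
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf(
    "<trace_summary> mean %.3f mm/s, peak %.3f, trough %.3f, pulsatility %.3f (%d points, %d outliers)\n",
    x$mean_mm_s, x$peak_mm_s, x$trough_mm_s, x$pulsatility,
    x$n_points, x$n_outliers))
  invisible(x)
}

#' Discrepancy between two velocity traces
#'
#' Interpolates trace \code{b} onto \code{a}'s time points and reports the
#' mean absolute velocity difference as a percentage of the standard
#' deviation of \code{a}'s velocity series. Flagged or non-finite points of
#' \code{a} are excluded.
#'
#' @param a,b \code{\link{velocity_trace}} objects on a common time support.
#' @return Discrepancy in percent.
#' @export
compare_traces <- function(a, b) {
  stopifnot(inherits(a, "velocity_trace"), inherits(b, "velocity_trace"))
  bok <- is.finite(b$velocity_mm_s)
  if (sum(bok) < 2L) stop("trace b has fewer than 2 usable points")
  vb <- stats::approx(b$time_s[bok], b$velocity_mm_s[bok],
                      xout = a$time_s, rule = 2)$y
  keep <- is.finite(a$velocity_mm_s) & !a$outlier_flag
  if (sum(keep) < 2L) stop("trace a has fewer than 2 usable points")
  sda <- stats::sd(a$velocity_mm_s[keep])
  if (sda == 0) stop("trace a has zero velocity standard deviation")
  100 * mean(abs(a$velocity_mm_s[keep] - vb[keep])) / sda
}

#' Locate zero crossings of a velocity trace
#'
#' Median-filters the usable points (so single noisy points near a reversal
#' do not generate spurious crossings), finds sign changes, then refines
#' each crossing time by a local straight-line fit of velocity against time.
#' The refinement matters because displacements below the pixel scale around
#' a reversal are noise-dominated: the line is anchored by the well-resolved
#' points on both flanks of the crossing.
#'
#' @param trace A \code{\link{velocity_trace}}.
#' @param smooth_width Odd median-filter width applied before coarse crossing
#'   detection; 1 disables smoothing.
#' @param refine_halfwidth_s Half-width (seconds) of the window used for the
#'   local linear refinement; 0 disables refinement.
#' @param min_excursion_mm_s Hysteresis: a crossing counts only if the
#'   smoothed trace reaches at least this magnitude on both sides before the
#'   neighbouring crossings. Suppresses spurious crossings from noise
#'   wiggling about zero. 0 disables.
#' @return Numeric vector of crossing times in seconds (possibly empty).
#' @export
zero_crossings <- function(trace, smooth_width = 51L, refine_halfwidth_s = 0.1,
                           min_excursion_mm_s = 0) {
  stopifnot(inherits(trace, "velocity_trace"))
  keep <- is.finite(trace$velocity_mm_s) & !trace$outlier_flag
  t <- trace$time_s[keep]
  v_raw <- trace$velocity_mm_s[keep]
  if (length(v_raw) < 2L) return(numeric(0))
  smooth_width <- min(as.integer(smooth_width),
                      length(v_raw) - (1L - length(v_raw) %% 2L))
  v <- if (smooth_width >= 3L) {
    stats::runmed(v_raw, smooth_width, endrule = "median")
  } else v_raw
  s <- sign(v)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(numeric(0))
  cross <- nz[which(diff(s[nz]) != 0)]
  if (min_excursion_mm_s > 0 && length(cross)) {
    # segment boundaries: start of trace, each crossing, end of trace
    bounds <- c(0L, cross, length(v))
    seg_ok <- vapply(seq_len(length(bounds) - 1L), function(k) {
      seg <- v[(bounds[k] + 1L):bounds[k + 1L]]
      max(abs(seg)) >= min_excursion_mm_s
    }, TRUE)
    keep_cross <- seg_ok[-length(seg_ok)] & seg_ok[-1L]
    cross <- cross[keep_cross]
    if (!length(cross)) return(numeric(0))
  }
  coarse <- vapply(cross, function(i) {
    j <- nz[match(i, nz) + 1L]
    t[i] + (0 - v[i]) * (t[j] - t[i]) / (v[j] - v[i])
  }, 0)
  if (refine_halfwidth_s <= 0) return(coarse)
  vapply(coarse, function(t0) {
    win <- abs(t - t0) <= refine_halfwidth_s
    if (sum(win) < 5L) return(t0)
    d <- (t[win] - t0) / refine_halfwidth_s
    w <- (1 - abs(d)^3)^3  # tricube: downweights the window ends, where
                           # pulsatile wiggle would otherwise bias the line
    fit <- stats::lm.wfit(cbind(1, t[win] - t0), v_raw[win], w)
    b <- fit$coefficients
    if (!is.finite(b[2L]) || b[2L] == 0) return(t0)
    refined <- t0 - b[1L] / b[2L]
    # keep the refinement honest: never move outside the fit window
    if (abs(refined - t0) > refine_halfwidth_s) t0 else refined
  }, 0)
}
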