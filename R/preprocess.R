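#' Subtract the time-averaged background
#'
#' Removes the stationary component of a space-time image by subtracting each
#' column's temporal mean. Static structures in the light path (absorbers,
#' vessel walls) contribute a time-invariant stripe that would otherwise
#' dominate the cross-correlation at lag zero; moving particles survive the
#' subtraction because they occupy any one column only transiently.
#'
#' @param series A raw \code{\link{line_scan_series}} (not yet
#'   background-removed; subtracting twice is almost always a pipeline bug,
#'   so it is an error rather than a silent no-op).
#' @return The background-removed series (every column's time-mean is 0).
#' @export
subtract_background <- function(series) {
  stopifnot(inherits(series, "line_scan_series"))
  if (series$background_removed) {
    stop("background already subtracted from this series")
  }
  mu <- colMeans(series$data)
  out <- series
  out$data <- sweep(series$data, 2L, mu, "-")
  out$background_removed <- TRUE
  out
}

#' Extract a region of interest
#'
#' Keeps columns \code{[start_px, end_px)} (0-based, half-open) of the
#' space-time image. A 50 um or longer straight segment is typical for
#' arteries; ~10 um for capillaries.
#'
#' @param series A \code{\link{line_scan_series}}.
#' @param start_px,end_px 0-based half-open column range;
#'   \code{0 <= start_px < end_px <= L}.
#' @return The cropped series with \code{roi_origin_px} advanced by
#'   \code{start_px}.
#' @export
extract_roi <- function(series, start_px, end_px) {
  stopifnot(inherits(series, "line_scan_series"))
  L <- ncol(series$data)
  start_px <- as.integer(start_px); end_px <- as.integer(end_px)
  if (is.na(start_px) || is.na(end_px) || start_px < 0L || end_px > L ||
      start_px >= end_px) {
    stop(sprintf(
      "invalid ROI [%s, %s): need 0 <= start_px < end_px <= %d",
      start_px, end_px, L))
  }
  out <- series
  out$data <- series$data[, (start_px + 1L):end_px, drop = FALSE]
  out$roi_origin_px <- series$roi_origin_px + start_px
  if (ncol(out$data) < 4L) stop("ROI narrower than 4 columns is not analyzable")
  out
}

# Expected separation (in noise-sd units) between the upper- and
# lower-quartile means of pure Gaussian noise: 2 * dnorm(qnorm(0.75)) / 0.25.
.pure_noise_quartile_sep <- 2 * stats::dnorm(stats::qnorm(0.75)) / 0.25

#' Estimate the signal-to-noise ratio of raw line-scan data
#'
#' Operational SNR: the contrast between plasma (bright) and particle (dark)
#' intensity levels, relative to the noise standard deviation. The plasma
#' level is the mean of pixels at or above the upper quartile, the particle
#' level the mean at or below the lower quartile, and the noise sd is a
#' robust (MAD-based) estimate from temporal first differences of each
#' column, divided by \code{sqrt(2)}. Because pure noise alone separates the
#' two quartile means by ~2.54 sd, that bias is removed in quadrature, so a
#' particle-free noise image scores ~0 rather than ~2.5.
#'
#' @param series A raw \code{\link{line_scan_series}} containing both
#'   particle and plasma pixels. Background-subtracted input is refused (the
#'   quartile contrast is only meaningful on raw intensities).
#' @return A single non-negative number; \code{Inf} when the noise estimate
#'   is exactly zero (noiseless data).
#' @export
estimate_snr <- function(series) {
  stopifnot(inherits(series, "line_scan_series"))
  if (series$background_removed) {
    stop("estimate_snr needs raw (not background-subtracted) data")
  }
  x <- series$data
  if (max(x) == min(x)) stop("no contrast: series has zero intensity variance")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  plasma <- mean(x[x >= q[2L]])
  particle <- mean(x[x <= q[1L]])
  d <- x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  sigma <- stats::mad(as.vector(d), center = 0) / sqrt(2)
  if (sigma == 0) return(Inf)
  raw <- (plasma - particle) / sigma
  sqrt(max(raw^2 - .pure_noise_quartile_sep^2, 0))
}
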