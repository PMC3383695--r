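#' Brute-force spatial cross-correlation (oracle)
#'
#' Direct O(L^2) cross-correlation over every integer lag in
#' \code{[-(L-1), L-1]} with zero outside the support, plus a 3-point
#' parabolic sub-pixel refinement at the argmax. Deliberately naive and
#' independent of the Fourier path: it is the reference the fast
#' implementation is tested against.
#'
#' @param row_a,row_b Equal-length numeric vectors (length >= 4).
#' @return List with \code{correlogram}, \code{lag_axis} and
#'   \code{best_shift}. Positive \code{best_shift} means \code{row_b} is
#'   \code{row_a} translated toward increasing index.
#' @export
brute_force_correlate <- function(row_a, row_b) {
  L <- length(row_a)
  if (length(row_b) != L) stop("rows must have equal length")
  if (L < 4L) stop("rows must have length >= 4")
  lags <- seq.int(-(L - 1L), L - 1L)
  corr <- vapply(lags, function(l) {
    xs <- max(1L, 1L - l):min(L, L - l)
    sum(row_a[xs] * row_b[xs + l])
  }, 0)
  mx <- max(corr)
  cand <- which(corr == mx)
  idx <- cand[which.min(abs(lags[cand]))]
  best <- as.numeric(lags[idx])
  if (idx > 1L && idx < length(corr)) {
    ym <- corr[idx - 1L]; y0 <- corr[idx]; yp <- corr[idx + 1L]
    den <- ym - 2 * y0 + yp
    if (den < 0) best <- best + 0.5 * (ym - yp) / den
  }
  list(correlogram = corr, lag_axis = lags, best_shift = best)
}

#' Score an estimated trace against ground truth
#'
#' Interpolates the truth onto the estimate's time points and computes the
#' per-point relative error \code{|v_hat - v| / max(|v|, v_floor)} over
#' unflagged points; \code{v_floor} keeps the ratio meaningful near flow
#' reversal. Points are binned by true speed into equal-width bins and the
#' largest true speed whose bin passes the tolerance is reported.
#'
#' @param estimate A \code{\link{velocity_trace}} from the analysis.
#' @param truth The generator's ground-truth \code{\link{velocity_trace}}.
#' @param tolerance_pct Bin pass tolerance on the median relative error
#'   (percent).
#' @param n_speed_bins Number of equal-width true-speed bins.
#' @param v_floor Relative-error denominator floor, mm/s.
#' @return An object of class \code{accuracy_report}:
#'   \code{median_rel_error_pct}, \code{p95_rel_error_pct},
#'   \code{max_speed_within_tol_mm_s}, \code{outlier_rate_pct},
#'   \code{n_points}, plus per-bin detail in \code{bins}.
#' @export
score_accuracy <- function(estimate, truth, tolerance_pct = 5,
                           n_speed_bins = 20L, v_floor = 0.5) {
  stopifnot(inherits(estimate, "velocity_trace"),
            inherits(truth, "velocity_trace"))
  if (any(truth$outlier_flag)) stop("truth trace must have no flagged points")
  vt <- stats::approx(truth$time_s, truth$velocity_mm_s,
                      xout = estimate$time_s, rule = 2)$y
  ok <- !estimate$outlier_flag & is.finite(estimate$velocity_mm_s)
  if (!any(ok)) stop("no unflagged points to score")
  err_pct <- 100 * abs(estimate$velocity_mm_s[ok] - vt[ok]) /
    pmax(abs(vt[ok]), v_floor)
  speed <- abs(vt[ok])
  rng <- range(speed)
  if (rng[2L] > rng[1L]) {
    breaks <- seq(rng[1L], rng[2L], length.out = n_speed_bins + 1L)
    bin <- cut(speed, breaks, include.lowest = TRUE)
  } else {
    bin <- factor(rep(1L, length(speed)))
  }
  med_by_bin <- tapply(err_pct, bin, stats::median)
  max_by_bin <- tapply(speed, bin, max)
  used <- !is.na(med_by_bin)
  pass <- used & med_by_bin <= tolerance_pct
  structure(
    list(median_rel_error_pct = stats::median(err_pct),
         p95_rel_error_pct = unname(stats::quantile(err_pct, 0.95)),
         max_speed_within_tol_mm_s = if (any(pass)) max(max_by_bin[pass]) else NA_real_,
         outlier_rate_pct = 100 * mean(!ok),
         n_points = sum(ok),
         tolerance_pct = tolerance_pct,
         bins = data.frame(bin = names(med_by_bin)[used],
                           max_speed_mm_s = unname(max_by_bin[used]),
                           median_rel_error_pct = unname(med_by_bin[used]))),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> median err %.3g%%, p95 %.3g%%, accurate to %.4g mm/s (<= %.3g%%), outliers %.3g%%, n = %d\n",
    x$median_rel_error_pct, x$p95_rel_error_pct,
    x$max_speed_within_tol_mm_s, x$tolerance_pct,
    x$outlier_rate_pct, x$n_points))
  invisible(x)
}
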