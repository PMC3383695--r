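#' Row-wise Fourier transform of a space-time image
#'
#' Zero-pads every scan row to \code{pad_to} samples and takes its 1-D DFT
#' along the spatial axis. Padding to at least \code{2L - 1} makes the
#' subsequent Fourier-domain product a linear (not circular) correlation:
#' particles that leave or enter the region of interest must not wrap around
#' the lag axis, or high speeds would alias.
#'
#' @param series A background-subtracted \code{\link{line_scan_series}}.
#' @param pad_to Transform length; default is the next power of two at or
#'   above \code{2L - 1}. Must be \code{>= 2L - 1}.
#' @return An object of class \code{fourier_line_series} with complex
#'   coefficient matrix \code{coeffs} (T x pad_to).
#' @export
fft_rows <- function(series, pad_to = NULL) {
  stopifnot(inherits(series, "line_scan_series"))
  if (!series$background_removed) {
    stop("fft_rows expects a background-subtracted series")
  }
  L <- ncol(series$data)
  min_pad <- 2L * L - 1L
  if (is.null(pad_to)) pad_to <- 2L^ceiling(log2(min_pad))
  pad_to <- as.integer(pad_to)
  if (pad_to < min_pad) {
    stop(sprintf("pad_to (%d) must be >= 2L - 1 = %d for linear correlation",
                 pad_to, min_pad))
  }
  X <- series$data
  T_ <- nrow(X)
  coeffs <- matrix(0 + 0i, T_, pad_to)
  chunk <- 4096L
  for (i0 in seq(1L, T_, by = chunk)) {
    idx <- i0:min(T_, i0 + chunk - 1L)
    Xp <- matrix(0, pad_to, length(idx))
    Xp[seq_len(L), ] <- t(X[idx, , drop = FALSE])
    coeffs[idx, ] <- t(stats::mvfft(Xp))
  }
  structure(
    list(coeffs = coeffs, n_space = L, pad = pad_to,
         calibration = series$calibration,
         roi_origin_px = series$roi_origin_px,
         row_offset = 0L),
    class = "fourier_line_series"
  )
}

#' @export
print.fourier_line_series <- function(x, ...) {
  cat(sprintf("<fourier_line_series> %d rows, %d px padded to %d, row offset %d\n",
              nrow(x$coeffs), x$n_space, x$pad, x$row_offset))
  invisible(x)
}

#' Inverse of \code{\link{fft_rows}} (spatial rows, unpadded)
#'
#' @param F A \code{fourier_line_series}.
#' @return Real matrix of the first \code{n_space} samples of each row.
#' @export
ifft_rows <- function(F) {
  stopifnot(inherits(F, "fourier_line_series"))
  out <- Re(t(stats::mvfft(t(F$coeffs), inverse = TRUE))) / F$pad
  out[, seq_len(F$n_space), drop = FALSE]
}

#' Split a Fourier series into a delayed scan pair
#'
#' Pairs every scan with its Nth later neighbour: the reference view keeps
#' rows \code{0 .. T-1-N}, the delayed view rows \code{N .. T-1} (0-based),
#' yielding \code{T - N} pairs. Fast flows need only \code{N = 1}; slow
#' capillary flows use larger N so the per-pair displacement exceeds pixel
#' resolution.
#'
#' @param F A \code{fourier_line_series}.
#' @param delay_steps Positive integer \code{N < T}.
#' @return List with elements \code{reference}, \code{delayed} (both
#'   \code{fourier_line_series}) and \code{delay_steps}.
#' @export
make_delayed_pairs <- function(F, delay_steps) {
  stopifnot(inherits(F, "fourier_line_series"))
  N <- as.integer(delay_steps)
  T_ <- nrow(F$coeffs)
  if (is.na(N) || N < 1L || N >= T_) {
    stop(sprintf("delay_steps must satisfy 1 <= N <= T - 1 = %d", T_ - 1L))
  }
  reference <- F
  reference$coeffs <- F$coeffs[seq_len(T_ - N), , drop = FALSE]
  delayed <- F
  delayed$coeffs <- F$coeffs[(N + 1L):T_, , drop = FALSE]
  delayed$row_offset <- F$row_offset + N
  list(reference = reference, delayed = delayed, delay_steps = N)
}

#' Symmetric phase-weighted cross-correlation of delayed scan pairs
#'
#' For each pair and each spatial frequency k computes
#' \deqn{G_k = \frac{\bar S_{1,k} S_{2,k}}{(|S_{1,k}||S_{2,k}| + \epsilon)^\alpha}}
#' then inverse-transforms along k and centres the lag axis. The denominator
#' whitens both spectra symmetrically: at \code{alpha = 1} only phase is kept
#' (sharpest peak, strongest side-lobe suppression); \code{alpha = 0} is the
#' plain cross-correlation. Positive lags correspond to motion toward
#' increasing column index.
#'
#' @param reference,delayed Matching \code{fourier_line_series} from
#'   \code{\link{make_delayed_pairs}}.
#' @param phase_exponent Filter exponent \code{alpha} in \code{[0, 1]}.
#' @param epsilon Regularizer added to the magnitude product before raising
#'   to \code{alpha}; default \code{1e-6 * max(|S1||S2|)}.
#' @param lowpass_sigma_px Width (in pixels, spatial domain) of a Gaussian
#'   spectral low-pass applied with the whitening (raised to the same
#'   \code{alpha}). Whitening alone weights every frequency bin equally,
#'   including bins beyond the particle band that carry only boundary and
#'   discretization junk; restricting the whitened spectrum to physically
#'   meaningful wavelengths is part of the symmetric phase-filter design.
#'   Set to 0 to disable.
#' @return An object of class \code{correlogram_stack}: matrix
#'   \code{correlograms} (pairs x \code{2L - 1} lags), \code{lag_axis} in
#'   pixels (0 at the centre), \code{time_axis} in seconds of each reference
#'   scan.
#' @export
phase_correlate <- function(reference, delayed, phase_exponent = 1,
                            epsilon = NULL, lowpass_sigma_px = 1) {
  stopifnot(inherits(reference, "fourier_line_series"),
            inherits(delayed, "fourier_line_series"))
  if (!identical(dim(reference$coeffs), dim(delayed$coeffs)) ||
      reference$n_space != delayed$n_space) {
    stop("reference and delayed series have mismatched shapes")
  }
  alpha <- phase_exponent
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("phase_exponent must lie in [0, 1]")
  }
  S1 <- reference$coeffs
  S2 <- delayed$coeffs
  G <- Conj(S1) * S2
  if (alpha > 0) {
    mag <- Mod(S1) * Mod(S2)
    if (is.null(epsilon)) {
      epsilon <- 1e-6 * max(mag)
      if (epsilon == 0) epsilon <- .Machine$double.xmin  # all-zero spectra
    }
    if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
    G <- G / (mag + epsilon)^alpha
    if (lowpass_sigma_px > 0) {
      P <- ncol(G)
      k <- c(0:(P %/% 2), seq.int(-(P - P %/% 2 - 1L), -1L))
      H <- exp(-(2 * pi * k / P)^2 * lowpass_sigma_px^2 / 2)
      G <- G * rep(H^alpha, each = nrow(G))
    }
  } else if (!is.null(epsilon) && epsilon <= 0) {
    stop("epsilon must be > 0")
  }
  M <- nrow(G)
  P <- ncol(G)
  L <- reference$n_space
  corr <- matrix(0, M, 2L * L - 1L)
  chunk <- 4096L
  for (i0 in seq(1L, M, by = chunk)) {
    idx <- i0:min(M, i0 + chunk - 1L)
    Ci <- Re(stats::mvfft(t(G[idx, , drop = FALSE]), inverse = TRUE)) / P
    # DFT index m holds lag m (mod P): positive lags 0..L-1 sit at the head,
    # negative lags -(L-1)..-1 at the tail.
    corr[idx, ] <- t(rbind(Ci[(P - L + 2L):P, , drop = FALSE],
                           Ci[seq_len(L), , drop = FALSE]))
  }
  N <- delayed$row_offset - reference$row_offset
  rate <- reference$calibration$line_rate_hz
  # Each correlogram measures the displacement accrued over [t, t + N/rate];
  # stamping it at the interval midpoint keeps pulsatile traces phase-aligned
  # with the truth even for large delays.
  structure(
    list(correlograms = corr,
         lag_axis = seq.int(-(L - 1L), L - 1L),
         time_axis = (reference$row_offset + seq_len(M) - 1L + N / 2) / rate,
         normalized = FALSE,
         delay_steps = as.integer(N),
         n_space = L,
         calibration = reference$calibration),
    class = "correlogram_stack"
  )
}

#' @export
print.correlogram_stack <- function(x, ...) {
  cat(sprintf("<correlogram_stack> %d correlograms x %d lags, delay %d%s\n",
              nrow(x$correlograms), length(x$lag_axis), x$delay_steps,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Average consecutive correlogram frames
#'
#' Replaces non-overlapping groups of \code{window} consecutive correlograms
#' by their mean, raising the correlation SNR at the cost of temporal
#' resolution (a trailing partial group is dropped). With a 2600 Hz line rate,
#' \code{window = 26} yields the reduced-resolution 100 velocity-points/s
#' mode.
#'
#' @param stack A \code{correlogram_stack}.
#' @param window Positive integer \code{W <= M}.
#' @return The averaged stack; each group's time is the group's mean time.
#' @export
average_frames <- function(stack, window) {
  stopifnot(inherits(stack, "correlogram_stack"))
  W <- as.integer(window)
  M <- nrow(stack$correlograms)
  if (is.na(W) || W < 1L || W > M) {
    stop(sprintf("window must satisfy 1 <= W <= %d", M))
  }
  if (W == 1L) return(stack)
  n_g <- M %/% W
  keep <- seq_len(n_g * W)
  grp <- rep(seq_len(n_g), each = W)
  out <- stack
  out$correlograms <- rowsum(stack$correlograms[keep, , drop = FALSE], grp,
                             reorder = FALSE) / W
  out$time_axis <- as.vector(rowsum(stack$time_axis[keep], grp,
                                    reorder = FALSE)) / W
  out
}

#' Normalize each correlogram to a probability distribution
#'
#' Per row: subtract the row minimum and divide by the row sum, so every row
#' is non-negative and sums to 1 (an all-constant row becomes uniform). A
#' monotone per-row transform: peak locations are unchanged.
#'
#' @param stack An un-normalized \code{correlogram_stack}.
#' @return The normalized stack (\code{normalized = TRUE}).
#' @export
normalize_to_probability <- function(stack) {
  stopifnot(inherits(stack, "correlogram_stack"))
  if (stack$normalized) stop("stack is already normalized")
  X <- stack$correlograms
  mn <- apply(X, 1L, min)
  X <- X - mn
  s <- rowSums(X)
  flat <- s == 0
  if (any(flat)) {
    X[flat, ] <- 1
    s[flat] <- ncol(X)
  }
  out <- stack
  out$correlograms <- X / s
  out$normalized <- TRUE
  out
}

#' Fit a Gaussian to a correlogram peak for sub-pixel shift estimation
#'
#' Locates the global maximum (ties broken toward the smallest \code{|lag|}),
#' then least-squares fits a four-parameter Gaussian (amplitude, centre,
#' width, offset) to the \code{2w + 1} samples around it. Falls back to
#' 3-point log-parabolic interpolation when the fit does not converge. Peaks
#' whose maximum lies within \code{w} samples of the lag-axis boundary are
#' reported as failures: the displacement is outside the measurable range.
#'
#' @param row Numeric correlogram (one row of a stack).
#' @param lag_axis Integer lag of each sample (defaults to a centred axis).
#' @param fit_halfwidth_px Fit window half-width \code{w}.
#' @return List with \code{shift_px} (fitted centre, \code{NA} on failure),
#'   \code{peak_quality} (\code{1 - residual RMS / amplitude}, clamped to
#'   \code{[0, 1]}), and \code{failed}.
#' @export
fit_peak <- function(row, lag_axis = NULL, fit_halfwidth_px = 4L) {
  w <- as.integer(fit_halfwidth_px)
  n <- length(row)
  if (n < 2L * w + 1L) stop("correlogram shorter than fit window (2w + 1)")
  if (is.null(lag_axis)) {
    if (n %% 2L == 0L) stop("default lag_axis needs an odd-length row")
    lag_axis <- seq.int(-((n - 1L) %/% 2L), (n - 1L) %/% 2L)
  }
  failure <- list(shift_px = NA_real_, peak_quality = 0, failed = TRUE)
  if (!all(is.finite(row))) return(failure)
  mx <- max(row)
  if (mx == min(row)) return(failure)  # flat row: no peak
  cand <- which(row == mx)
  idx <- cand[which.min(abs(lag_axis[cand]))]
  if (idx <= w || idx > n - w) return(failure)  # shift out of measurable range
  win <- (idx - w):(idx + w)
  x <- as.numeric(lag_axis[win])
  y <- row[win]
  b0 <- min(y)
  A0 <- y[w + 1L] - b0
  p0 <- c(A = A0, c = as.numeric(lag_axis[idx]), s = max(1, w / 2), b = b0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) y - (p[4L] + p[1L] * exp(-(x - p[2L])^2 / (2 * p[3L]^2))),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$info %in% 1:4) {
    p <- fit$par
    if (is.finite(p[2L]) && p[1L] > 0 && abs(p[2L] - lag_axis[idx]) <= w) {
      rms <- sqrt(mean(fit$fvec^2))
      q <- 1 - rms / p[1L]
      return(list(shift_px = unname(p[2L]),
                  peak_quality = min(max(q, 0), 1), failed = FALSE))
    }
  }
  fit_peak_logparabolic(row, lag_axis, idx, w)
}

# 3-point log-parabolic fallback: exact for a sampled Gaussian on a baseline
# of zero; degrades gracefully to a plain parabola when logs are unusable.
fit_peak_logparabolic <- function(row, lag_axis, idx, w) {
  y3 <- row[(idx - 1L):(idx + 1L)] - min(row)
  delta <- if (all(y3 > 0) && (y3[1L] != y3[2L] || y3[3L] != y3[2L])) {
    l <- log(y3)
    den <- l[1L] - 2 * l[2L] + l[3L]
    if (den < 0) 0.5 * (l[1L] - l[3L]) / den else NA_real_
  } else {
    den <- y3[1L] - 2 * y3[2L] + y3[3L]
    if (den < 0) 0.5 * (y3[1L] - y3[3L]) / den else NA_real_
  }
  if (!is.finite(delta) || abs(delta) > 1) {
    return(list(shift_px = NA_real_, peak_quality = 0, failed = TRUE))
  }
  centre <- lag_axis[idx] + delta
  # quality from the implied Gaussian over the fit window
  win <- (idx - w):(idx + w)
  x <- as.numeric(lag_axis[win])
  yw <- row[win] - min(row)
  amp <- y3[2L]
  l <- log(pmax(y3, .Machine$double.xmin))
  curv <- -(l[1L] - 2 * l[2L] + l[3L]) / 2
  q <- if (curv > 0) {
    s2 <- 1 / (2 * curv)
    yhat <- amp * exp(-(x - centre)^2 / (2 * s2))
    1 - sqrt(mean((yw - yhat)^2)) / amp
  } else 0
  list(shift_px = unname(centre), peak_quality = min(max(q, 0), 1),
       failed = FALSE)
}

#' Peak-to-sidelobe ratio of a correlogram
#'
#' How far the global maximum stands above the rest of the correlogram:
#' \code{(peak - mean(off-peak)) / sd(off-peak)}, with an exclusion zone of
#' \code{exclude_halfwidth} samples around the peak. The standard detection
#' confidence for correlation peaks: a displacement estimate whose peak
#' barely exceeds the sidelobe floor is indistinguishable from noise.
#'
#' @param row Numeric correlogram.
#' @param exclude_halfwidth Samples on each side of the argmax excluded from
#'   the off-peak statistics.
#' @return A single number (\code{Inf} when the off-peak part is constant).
#' @export
peak_sidelobe_ratio <- function(row, exclude_halfwidth = 10L) {
  im <- which.max(row)
  excl <- max(1L, im - exclude_halfwidth):min(length(row), im + exclude_halfwidth)
  off <- row[-excl]
  if (length(off) < 3L) return(Inf)
  s <- stats::sd(off)
  if (s == 0) return(Inf)
  (row[im] - mean(off)) / s
}

#' Convert a pixel shift to velocity
#'
#' \code{v = shift_px * pixel_size_um * line_rate_hz / (1000 * delay_steps)}
#' in mm/s: displacement over the inter-pair interval divided by that
#' interval. Signed; positive = toward increasing column index.
#'
#' @param shift_px Fitted sub-pixel displacement (vectorized).
#' @param calibration A \code{\link{scan_calibration}}.
#' @param delay_steps Delay between the correlated pair, in scan intervals.
#' @return Velocity in mm/s.
#' @export
shift_to_velocity <- function(shift_px, calibration, delay_steps) {
  stopifnot(inherits(calibration, "scan_calibration"))
  N <- as.integer(delay_steps)
  if (is.na(N) || N < 1L) stop("delay_steps must be >= 1")
  shift_px * calibration$pixel_size_um * calibration$line_rate_hz / (1000 * N)
}

# Resolve the reference-row edge guard: NA means "auto" (one maximal
# red-cell support, capped at a sixth of the window per side).
resolve_edge_guard <- function(config, calibration, L) {
  g <- config$edge_guard_px
  if (is.na(g)) {
    g <- min(as.integer(ceiling(7 / calibration$pixel_size_um)), L %/% 6L)
  }
  min(as.integer(g), L %/% 6L)
}

# Zero `guard` columns at each end of every row (the asymmetric
# interrogation window: applied to the reference only). A short raised-cosine
# rolloff follows the zeroed region: a hard mask edge leaks across the
# spectrum and skews the whitened phase.
mask_reference_edges <- function(series, guard) {
  if (guard <= 0L) return(series)
  L <- ncol(series$data)
  w <- rep(1, L)
  w[seq_len(guard)] <- 0
  w[(L - guard + 1L):L] <- 0
  ramp <- min(4L, guard, (L - 2L * guard) %/% 2L)
  if (ramp > 0L) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
    w[guard + seq_len(ramp)] <- r
    w[L - guard + 1L - seq_len(ramp)] <- r
  }
  series$data <- sweep(series$data, 2L, w, "*")
  series
}

# Build a delayed pair whose reference rows are edge-guarded. `direction`
# controls which member of each pair plays the reference: "forward" pairs
# scan t (reference) with t+N, "reverse" pairs t+N (reference) with t.
guarded_delayed_pairs <- function(series, delay_steps, guard,
                                  direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  N <- as.integer(delay_steps)
  T_ <- nrow(series$data)
  if (N < 1L || N >= T_) {
    stop(sprintf("delay_steps must satisfy 1 <= N <= T - 1 = %d", T_ - 1L))
  }
  if (guard <= 0L && direction == "forward") {
    return(make_delayed_pairs(fft_rows(series), N))
  }
  ref_rows <- if (direction == "forward") seq_len(T_ - N) else (N + 1L):T_
  del_rows <- if (direction == "forward") (N + 1L):T_ else seq_len(T_ - N)
  ref_series <- mask_reference_edges(series, guard)
  ref_series$data <- ref_series$data[ref_rows, , drop = FALSE]
  del_series <- series
  del_series$data <- series$data[del_rows, , drop = FALSE]
  reference <- fft_rows(ref_series)
  delayed <- fft_rows(del_series)
  reference$row_offset <- if (direction == "forward") 0L else N
  delayed$row_offset <- if (direction == "forward") N else 0L
  list(reference = reference, delayed = delayed, delay_steps = N)
}

# Correlogram stack for piv_analyze: forward pass, optionally averaged with
# the lag-mirrored reverse pass (central-difference-style bias cancellation).
build_correlogram_stack <- function(series, delay_steps, guard, config) {
  pairs <- guarded_delayed_pairs(series, delay_steps, guard, "forward")
  stack <- phase_correlate(pairs$reference, pairs$delayed, config$phase_exponent)
  if (config$symmetric_pairing) {
    rm(pairs)
    rpairs <- guarded_delayed_pairs(series, delay_steps, guard, "reverse")
    rstack <- phase_correlate(rpairs$reference, rpairs$delayed,
                              config$phase_exponent)
    rm(rpairs)
    nl <- ncol(rstack$correlograms)
    stack$correlograms <- (stack$correlograms +
                             rstack$correlograms[, nl:1L, drop = FALSE]) / 2
  }
  stack
}

#' Choose the scan-pair delay for slow flows
#'
#' Runs a pilot pass on a subsample of pairs at \code{N = 1}; while the
#' median absolute fitted shift is below \code{min_shift_px}, the delay is
#' doubled (1, 2, 4, ... up to \code{max_delay_steps}). Capillary flows that
#' move a fraction of a pixel per scan thereby get the Nth-neighbour pairing
#' needed to resolve their displacement.
#'
#' @param series A preprocessed (background-subtracted, ROI-cropped)
#'   \code{\link{line_scan_series}}.
#' @param config An \code{\link{analysis_config}} (uses \code{min_shift_px},
#'   \code{max_delay_steps}, \code{phase_exponent}, \code{fit_halfwidth_px}).
#' @param n_pilot Number of evenly spaced pilot pairs per candidate delay.
#' @param verbose Log the pilot medians?
#' @return The chosen integer delay. Zero flow returns \code{max_delay_steps}
#'   with a warning.
#' @export
select_delay <- function(series, config = analysis_config(), n_pilot = 64L,
                         verbose = FALSE) {
  stopifnot(inherits(series, "line_scan_series"))
  guard <- resolve_edge_guard(config, series$calibration, ncol(series$data))
  F <- fft_rows(series)
  FM <- if (guard > 0L) fft_rows(mask_reference_edges(series, guard)) else F
  T_ <- nrow(F$coeffs)
  N <- 1L
  repeat {
    if (N >= T_) break
    refs <- unique(round(seq(1L, T_ - N, length.out = min(n_pilot, T_ - N))))
    ref <- FM; ref$coeffs <- FM$coeffs[refs, , drop = FALSE]
    del <- F; del$coeffs <- F$coeffs[refs + N, , drop = FALSE]
    del$row_offset <- N
    stack <- phase_correlate(ref, del, config$phase_exponent)
    stack <- normalize_to_probability(stack)
    shifts <- vapply(seq_len(nrow(stack$correlograms)), function(i) {
      fit_peak(stack$correlograms[i, ], stack$lag_axis,
               config$fit_halfwidth_px)$shift_px
    }, 0)
    med <- stats::median(abs(shifts), na.rm = TRUE)
    if (is.na(med)) med <- 0
    if (verbose) {
      message(sprintf("[lspiv] select_delay pilot: N=%d median |shift|=%.3f px",
                      N, med))
    }
    if (med >= config$min_shift_px) return(N)
    if (N >= config$max_delay_steps) break
    N <- min(N * 2L, config$max_delay_steps)
  }
  warning(sprintf(
    "pilot shifts below %.3g px even at max delay; returning max_delay_steps = %d (flow may be unresolvably slow or absent)",
    config$min_shift_px, config$max_delay_steps))
  config$max_delay_steps
}

#' Run the full velocimetry pipeline
#'
#' Composes the whole method end to end: background subtraction, ROI crop,
#' row-wise FFT, delayed-pair construction (with automatic delay selection
#' when \code{delay_steps} is \code{NA}), symmetric phase-weighted
#' cross-correlation, frame averaging down to the requested velocity-point
#' rate, probability normalization, Gaussian sub-pixel peak fitting, shift to
#' velocity conversion, and running-window outlier flagging. Rows whose peak
#' fit fails carry \code{NA} velocity, quality 0 and an outlier flag.
#'
#' @param series A \code{\link{line_scan_series}} (raw or already
#'   background-subtracted).
#' @param config An \code{\link{analysis_config}}.
#' @param verbose Emit structured log lines?
#' @return A \code{\link{velocity_trace}} with the calibration, chosen delay
#'   and config attached as attributes.
#' @export
piv_analyze <- function(series, config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(series, "line_scan_series"),
            inherits(config, "analysis_config"))
  cal <- series$calibration
  if (!series$background_removed) series <- subtract_background(series)
  L_full <- ncol(series$data)
  start <- config$roi_start_px
  end <- if (is.na(config$roi_end_px)) L_full else config$roi_end_px
  if (start != 0L || end != L_full) series <- extract_roi(series, start, end)
  N <- config$delay_steps
  if (is.na(N)) N <- select_delay(series, config, verbose = verbose)
  guard <- resolve_edge_guard(config, cal, ncol(series$data))
  stack <- build_correlogram_stack(series, N, guard, config)
  W <- config$frame_average_window
  if (is.na(W)) {
    W <- max(1L, as.integer(floor(cal$line_rate_hz /
                                    config$velocity_points_per_second)))
  }
  W <- min(W, nrow(stack$correlograms))
  if (W > 1L) stack <- average_frames(stack, W)
  stack <- normalize_to_probability(stack)
  M <- nrow(stack$correlograms)
  shift <- numeric(M); quality <- numeric(M); failed <- logical(M)
  for (i in seq_len(M)) {
    row <- stack$correlograms[i, ]
    f <- fit_peak(row, stack$lag_axis, config$fit_halfwidth_px)
    if (!f$failed && config$min_peak_psr > 0 &&
        peak_sidelobe_ratio(row) < config$min_peak_psr) {
      f$failed <- TRUE  # no detectable peak above the sidelobe floor
    }
    shift[i] <- f$shift_px; quality[i] <- f$peak_quality; failed[i] <- f$failed
  }
  vel <- shift_to_velocity(shift, cal, N)
  trace <- velocity_trace(stack$time_axis, vel, shift_px = shift,
                          peak_quality = quality, outlier_flag = failed,
                          calibration = cal, delay_steps = N)
  win <- config$outlier_window
  if (win > nrow(trace)) {
    win <- max(3L, nrow(trace) - (1L - nrow(trace) %% 2L))  # largest odd <= n
  }
  if (nrow(trace) >= 3L) {
    trace <- flag_outliers(trace, config$outlier_threshold_sd, win)
  }
  if (!is.null(config$median_filter_width) &&
      nrow(trace) >= config$median_filter_width) {
    trace <- median_filter_trace(trace, config$median_filter_width)
  }
  if (verbose) {
    message(sprintf(
      "[lspiv] analyze: delay_steps=%d roi=[%d,%d) frame_window=%d points=%d outliers=%d",
      N, start, end, W, nrow(trace), sum(trace$outlier_flag)))
  }
  attr(trace, "config") <- config
  trace
}
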