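#' Ground-truth velocity waveform
#'
#' A speed-versus-time law for the simulator: a linear ramp (or arbitrary
#' piecewise-linear base) multiplied by \code{1 + depth * sin(2 pi f t)}. The
#' 10 Hz default modulation emulates the mouse heartbeat seen in cortical
#' velocimetry.
#'
#' @param base_start,base_end Ramp endpoints in mm/s (signed; equal values
#'   give constant flow).
#' @param duration_s Waveform duration, seconds (> 0).
#' @param modulation_freq Modulation frequency, Hz.
#' @param modulation_depth Fractional modulation amplitude in \code{[0, 1)}.
#' @param base_times,base_values Optional piecewise-linear base: speed
#'   \code{base_values} (mm/s) at knots \code{base_times} (s), overriding the
#'   ramp. Negative values describe reversed flow.
#' @return An object of class \code{velocity_waveform}.
#' @export
make_waveform <- function(base_start, base_end = base_start, duration_s,
                          modulation_freq = 10, modulation_depth = 0,
                          base_times = NULL, base_values = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (modulation_depth < 0 || modulation_depth >= 1) {
    stop("modulation_depth must lie in [0, 1)")
  }
  if (is.null(base_times) != is.null(base_values)) {
    stop("base_times and base_values must be given together")
  }
  if (is.null(base_times)) {
    base_times <- c(0, duration_s)
    base_values <- c(base_start, base_end)
  }
  if (length(base_times) != length(base_values) || length(base_times) < 2L) {
    stop("piecewise base needs >= 2 matching knots")
  }
  if (any(!is.finite(base_times)) || any(!is.finite(base_values))) {
    stop("waveform knots must be finite")
  }
  structure(
    list(base_times = as.numeric(base_times),
         base_values = as.numeric(base_values),
         duration_s = as.numeric(duration_s),
         modulation_freq = as.numeric(modulation_freq),
         modulation_depth = as.numeric(modulation_depth),
         allow_reversal = any(base_values < 0)),
    class = "velocity_waveform"
  )
}

#' Evaluate a waveform at given times
#'
#' @param waveform A \code{\link{make_waveform}} object.
#' @param t Times in seconds.
#' @return Velocity in mm/s, \code{base(t) * (1 + depth * sin(2 pi f t))}.
#' @export
eval_waveform <- function(waveform, t) {
  stopifnot(inherits(waveform, "velocity_waveform"))
  base <- stats::approx(waveform$base_times, waveform$base_values,
                        xout = t, rule = 2)$y
  base * (1 + waveform$modulation_depth *
            sin(2 * pi * waveform$modulation_freq * t))
}

#' Synthetic line-scan scene
#'
#' Describes a simulated vessel: dark particles (emulating red blood cells)
#' of randomized size on a bright plasma background, advected by a known
#' velocity waveform, plus additive Gaussian noise calibrated to a target
#' SNR. The scene is the single source of ground truth for validation.
#'
#' @param waveform A \code{\link{make_waveform}}.
#' @param roi_length_um Length of the rendered region of interest, um.
#' @param duration_s Scene duration, seconds (defaults to the waveform's).
#' @param calibration A \code{\link{scan_calibration}}; default 0.5 um/px at
#'   2600 Hz.
#' @param particle_density_per_100um Expected number of particles per 100 um
#'   of vessel. Default 10 (one cell per ~10 um, a mid-range hematocrit);
#'   0 represents a transiently cell-free capillary.
#' @param particle_size_range_um Range the per-particle size is drawn from,
#'   uniformly; sizes are full widths at half depth. Default \code{c(1, 7)},
#'   covering red cells at varying orientation relative to the scan line.
#' @param plasma_level Background (plasma) intensity.
#' @param particle_contrast Dip depth of a particle centre below plasma; must
#'   lie in \code{(0, plasma_level]}.
#' @param target_snr \code{particle_contrast / noise_sd}; \code{Inf} means
#'   noiseless.
#' @param seed Integer seed; the same seed reproduces the scene bit for bit.
#' @return An object of class \code{synthetic_scene}.
#' @export
synthetic_scene <- function(waveform,
                            roi_length_um = 140,
                            duration_s = waveform$duration_s,
                            calibration = scan_calibration(0.5, 2600),
                            particle_density_per_100um = 10,
                            particle_size_range_um = c(1, 7),
                            plasma_level = 100,
                            particle_contrast = 50,
                            target_snr = Inf,
                            seed = 1L) {
  stopifnot(inherits(waveform, "velocity_waveform"),
            inherits(calibration, "scan_calibration"))
  if (roi_length_um <= 0) stop("roi_length_um must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (particle_density_per_100um < 0) stop("particle density must be >= 0")
  r <- sort(as.numeric(particle_size_range_um))
  if (length(r) != 2L || r[1L] <= 0 || r[2L] >= roi_length_um + r[1L]) {
    stop("particle_size_range_um must be positive and below the ROI length")
  }
  if (particle_contrast <= 0 || particle_contrast > plasma_level) {
    stop("particle_contrast must lie in (0, plasma_level]")
  }
  if (!(is.infinite(target_snr) || target_snr > 0)) {
    stop("target_snr must be positive or Inf")
  }
  structure(
    list(waveform = waveform,
         roi_length_um = as.numeric(roi_length_um),
         duration_s = as.numeric(duration_s),
         calibration = calibration,
         particle_density_per_100um = as.numeric(particle_density_per_100um),
         particle_size_range_um = r,
         plasma_level = as.numeric(plasma_level),
         particle_contrast = as.numeric(particle_contrast),
         target_snr = as.numeric(target_snr),
         seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %.4g um ROI, %.3g s @ %.6g Hz, density %.3g/100um, SNR %s, seed %d\n",
    x$roi_length_um, x$duration_s, x$calibration$line_rate_hz,
    x$particle_density_per_100um,
    if (is.infinite(x$target_snr)) "Inf" else format(x$target_snr), x$seed))
  invisible(x)
}

#' Render noiseless line-scans from a scene
#'
#' Particles are placed uniformly at random on an extended domain (the ROI
#' plus an inflow margin at least as wide as the largest per-scan
#' displacement plus the largest particle half-support). Every scan row
#' renders intensity as the plasma level minus a raised-cosine dip per
#' particle, evaluated at the particle's current sub-pixel position; between
#' rows every particle advances by \code{v(t) / line_rate}. Particles are
#' recycled periodically through the extended domain, which keeps the
#' expected density stationary for either flow direction. The ground-truth
#' trace records the waveform exactly - it is never quantized to the pixel
#' grid.
#'
#' @param scene A \code{\link{synthetic_scene}}.
#' @return List with \code{series} (noiseless \code{line_scan_series}, the
#'   scene attached as attribute \code{"scene"} and the particle draws as
#'   attribute \code{"particles"}) and \code{truth} (a
#'   \code{\link{velocity_trace}} with one exact point per scan).
#' @export
render_linescans <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cal <- scene$calibration
  px <- cal$pixel_size_um
  rate <- cal$line_rate_hz
  T_ <- max(2L, as.integer(round(scene$duration_s * rate)))
  L <- as.integer(round(scene$roi_length_um / px))
  if (L < 4L) stop("ROI shorter than 4 pixels")
  t <- (seq_len(T_) - 1L) / rate
  v <- eval_waveform(scene$waveform, t)             # mm/s
  disp_um <- v * 1000 / rate                        # um per scan
  max_disp <- max(abs(disp_um))
  roi_um <- L * px
  if (max_disp > roi_um) {
    stop(sprintf(
      "velocity unresolvable at this ROI/rate: per-scan displacement %.3g um exceeds ROI length %.3g um",
      max_disp, roi_um))
  }
  smax <- scene$particle_size_range_um[2L]
  margin <- max_disp + smax
  dom_min <- -margin
  dom_len <- roi_um + 2 * margin
  n_par <- as.integer(round(scene$particle_density_per_100um * dom_len / 100))
  M <- matrix(0, T_, L)
  sizes <- numeric(0); x0 <- numeric(0)
  if (n_par > 0L) {
    set.seed(scene$seed)
    x0 <- stats::runif(n_par, dom_min, dom_min + dom_len)
    sizes <- stats::runif(n_par, scene$particle_size_range_um[1L],
                          scene$particle_size_range_um[2L])
    D <- cumsum(c(0, disp_um[-T_]))                 # cumulative drift, um
    K <- as.integer(ceiling(smax / px)) + 1L
    offsets <- -K:K
    tt <- seq_len(T_)
    for (p in seq_len(n_par)) {
      cp <- ((x0[p] + D - dom_min) %% dom_len) + dom_min
      s <- sizes[p]
      j0 <- round(cp / px + 0.5)
      for (o in offsets) {
        j <- j0 + o
        u <- (j - 0.5) * px - cp
        sel <- j >= 1 & j <= L & abs(u) <= s
        if (any(sel)) {
          lin <- (j[sel] - 1L) * T_ + tt[sel]
          M[lin] <- M[lin] + 0.5 * (1 + cos(pi * u[sel] / s))
        }
      }
    }
  }
  # Occlusion saturates: overlapping cells cannot darken a pixel beyond one
  # fully occluding cell, so the summed dip field is capped at 1.
  data <- scene$plasma_level - scene$particle_contrast * pmin(M, 1)
  series <- line_scan_series(data, cal)
  attr(series, "scene") <- scene
  attr(series, "particles") <- data.frame(x0_um = x0, size_um = sizes)
  truth <- velocity_trace(t, v,
                          shift_px = disp_um / px,
                          peak_quality = rep(1, T_),
                          outlier_flag = rep(FALSE, T_),
                          calibration = cal, delay_steps = 1L)
  list(series = series, truth = truth)
}

#' Add Gaussian noise calibrated to a target SNR
#'
#' Adds i.i.d. normal noise with \code{sd = particle_contrast / target_snr},
#' matching the contrast-over-noise definition used by
#' \code{\link{estimate_snr}}. \code{target_snr = Inf} returns the series
#' unchanged (bit-identical).
#'
#' @param series A noiseless \code{\link{line_scan_series}} (typically from
#'   \code{\link{render_linescans}}).
#' @param target_snr Positive target SNR or \code{Inf}.
#' @param contrast Particle contrast; defaults to the attached scene's.
#' @param seed Noise seed; defaults to the attached scene's seed + 1 so the
#'   particle draw and the noise draw are independent streams.
#' @return The noisy series (scene attributes preserved).
#' @export
add_noise <- function(series, target_snr, contrast = NULL, seed = NULL) {
  stopifnot(inherits(series, "line_scan_series"))
  if (!(is.infinite(target_snr) || (is.numeric(target_snr) && target_snr > 0))) {
    stop("target_snr must be positive or Inf")
  }
  if (is.infinite(target_snr)) return(series)
  scene <- attr(series, "scene")
  if (is.null(contrast)) {
    if (is.null(scene)) stop("contrast must be given when no scene is attached")
    contrast <- scene$particle_contrast
  }
  if (is.null(seed)) {
    if (is.null(scene)) stop("seed must be given when no scene is attached")
    seed <- scene$seed + 1L
  }
  sigma <- contrast / target_snr
  set.seed(as.integer(seed))
  noisy <- series
  noisy$data <- series$data +
    matrix(stats::rnorm(length(series$data), sd = sigma),
           nrow(series$data), ncol(series$data))
  noisy
}

#' Render a scene and apply its calibrated noise in one step
#'
#' @param scene A \code{\link{synthetic_scene}}.
#' @return List with \code{series} (noisy at the scene's \code{target_snr}),
#'   \code{clean} (noiseless) and \code{truth}.
#' @export
simulate_linescans <- function(scene) {
  r <- render_linescans(scene)
  list(series = add_noise(r$series, scene$target_snr),
       clean = r$series, truth = r$truth)
}
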