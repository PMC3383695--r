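test_that("waveforms combine a ramp with 10 Hz modulation", {
  wf <- make_waveform(2, 10, duration_s = 1, modulation_depth = 0)
  tt <- seq(0, 1, by = 0.01)
  expect_equal(eval_waveform(wf, tt), 2 + 8 * tt)     # pure ramp at depth 0
  wfm <- make_waveform(5, 5, duration_s = 1, modulation_freq = 10,
                       modulation_depth = 0.3)
  expect_identical(eval_waveform(wfm, 0), 5)           # v(0) = base_start
  # sine integrates away over whole cycles
  tc <- seq(0, 0.5, by = 1 / 2600); tc <- tc[-length(tc)]
  expect_equal(mean(eval_waveform(wfm, tc)), 5, tolerance = 1e-9)
  expect_error(make_waveform(1, 1, duration_s = 0), "duration")
  expect_error(make_waveform(1, 1, duration_s = 1, modulation_depth = 1),
               "modulation_depth")
})

test_that("zero velocity renders identical rows; truth is never quantized", {
  sim <- render_linescans(constant_scene(0, 50, Inf, 0.05, seed = 2))
  expect_true(all(apply(sim$series$data, 2, function(col) all(col == col[1]))))

  wf <- make_waveform(1, 9, duration_s = 0.1, modulation_freq = 10,
                      modulation_depth = 0.15)
  sc <- synthetic_scene(wf, roi_length_um = 50, target_snr = Inf, seed = 2)
  sim2 <- render_linescans(sc)
  t <- sim2$truth$time_s
  expect_identical(sim2$truth$velocity_mm_s, eval_waveform(wf, t))
})

test_that("integer per-scan displacement translates rows exactly", {
  # 2 px/scan at 0.5 um/px and 2600 Hz -> 2.6 mm/s
  sim <- render_linescans(constant_scene(2.6, 64, Inf, 0.008, seed = 5))
  m <- sim$series$data
  # recycled particles need time to drift into the ROI: with ~21 scans the
  # wrap front cannot reach past column 30, so compare the downstream part
  for (t in 2:nrow(m)) {
    expect_equal(m[t, 33:ncol(m)], m[t - 1, 31:(ncol(m) - 2)],
                 tolerance = 1e-12)
  }
})

test_that("per-scan displacement follows v / (rate * pixel size)", {
  # 10 mm/s at 2600 Hz and 0.5 um/px -> 7.6923 px per scan
  sim <- render_linescans(constant_scene(10, 140, Inf, 0.01, seed = 1))
  expect_equal(sim$truth$shift_px, rep(10 * 1000 / 2600 / 0.5, nrow(sim$truth)),
               tolerance = 1e-9)
})

test_that("rendered dip widths at half depth match the drawn 1-7 um sizes", {
  px <- 0.5
  n_measured <- 0
  for (seed in c(3, 9, 27, 81, 243, 729)) {
    wf <- make_waveform(0, 0, duration_s = 2 / 2600)
    sc <- synthetic_scene(wf, roi_length_um = 120, duration_s = 2 / 2600,
                          particle_density_per_100um = 1.5, target_snr = Inf,
                          seed = seed)
    sim <- render_linescans(sc)
    parts <- attr(sim$series, "particles")
    row <- sim$series$data[1, ]
    x <- (seq_along(row) - 0.5) * px
    for (p in seq_len(nrow(parts))) {
      s_p <- parts$size_um[p]; c_p <- parts$x0_um[p]
      if (c_p - s_p < 1 || c_p + s_p > 119) next          # fully visible
      others <- parts$x0_um[-p]
      if (any(abs(others - c_p) < s_p + max(parts$size_um))) next  # isolated
      half_level <- sc$plasma_level - sc$particle_contrast / 2
      below <- x[row <= half_level & abs(x - c_p) <= 1.5 * s_p]
      if (!length(below)) next
      width <- diff(range(below)) + px            # full width at half depth
      expect_lt(abs(width - s_p), 2 * px)         # within +-1 px of the size
      expect_gte(s_p, 1); expect_lte(s_p, 7)
      n_measured <- n_measured + 1
    }
  }
  expect_gte(n_measured, 3)  # the loop actually measured something
})

test_that("noise injection is SNR-calibrated and seed-deterministic", {
  clean <- render_linescans(constant_scene(0.5, 100, Inf, 0.5, seed = 7))$series
  expect_identical(add_noise(clean, Inf), clean)      # Inf -> bit-identical

  n1 <- add_noise(clean, 8)
  n2 <- add_noise(clean, 8)
  expect_identical(n1$data, n2$data)                  # same seed, same noise
  sigma_emp <- sd(n1$data - clean$data)
  expect_equal(sigma_emp, 50 / 8, tolerance = 0.02)   # contrast / SNR
  expect_error(add_noise(clean, -2), "target_snr")
})

test_that("scenes are reproducible bit for bit from their seed", {
  sc <- constant_scene(3, 80, 2, 0.1, seed = 99)
  a <- simulate_linescans(sc)
  b <- simulate_linescans(sc)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth, b$truth)
})

test_that("unresolvable velocities are refused at render time", {
  # 2600 mm/s at 2.6 kHz = 1000 um per scan > 140 um ROI
  expect_error(render_linescans(constant_scene(2600, 140, Inf, 0.01, seed = 1)),
               "unresolvable")
})

test_that("zero particle density renders pure plasma and analyze degrades gracefully", {
  wf <- make_waveform(5, 5, duration_s = 0.1)
  sc <- synthetic_scene(wf, roi_length_um = 50, duration_s = 0.1,
                        particle_density_per_100um = 0, target_snr = 8, seed = 4)
  sim <- simulate_linescans(sc)
  expect_true(all(render_linescans(sc)$series$data == 100))
  tr <- suppressWarnings(piv_analyze(sim$series, analysis_config(delay_steps = 1)))
  # no tracer content: the majority of points must be flagged as
  # non-detections rather than reported as confident velocities
  expect_gt(mean(tr$outlier_flag), 0.5)
})
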