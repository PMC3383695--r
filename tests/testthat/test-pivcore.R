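cal <- scan_calibration(0.5, 2600)

test_that("fft_rows is invertible and handles impulse/zero rows", {
  m <- rbind(rep(0, 16), c(rep(0, 5), 1, rep(0, 10)), rnorm(16))
  s <- line_scan_series(m, cal, background_removed = TRUE)
  F <- fft_rows(s)
  expect_gte(F$pad, 2 * 16 - 1)
  expect_true(all(F$coeffs[1, ] == 0))                        # zero row
  expect_equal(Mod(F$coeffs[2, ]), rep(1, F$pad), tolerance = 1e-12)  # impulse
  back <- ifft_rows(F)
  expect_equal(back, m, tolerance = 1e-9)                     # round trip
  expect_error(fft_rows(s, pad_to = 16), "2L - 1")
})

test_that("delayed pairs index reference and Nth-neighbour rows", {
  m <- matrix(rnorm(100 * 8), 100, 8)
  F <- fft_rows(line_scan_series(m, cal, background_removed = TRUE))
  p1 <- make_delayed_pairs(F, 1)
  expect_identical(nrow(p1$reference$coeffs), 99L)
  expect_equal(p1$delayed$coeffs[1, ], F$coeffs[2, ])

  # the capillary-style pairing: every scan with its 5th neighbour
  p5 <- make_delayed_pairs(F, 5)
  expect_identical(nrow(p5$reference$coeffs), 95L)
  expect_equal(p5$delayed$coeffs[1, ], F$coeffs[6, ])
  expect_equal(p5$reference$coeffs[1, ], F$coeffs[1, ])

  expect_error(make_delayed_pairs(F, 100), "delay_steps")
  expect_error(make_delayed_pairs(F, 0), "delay_steps")
})

test_that("phase correlation recovers identity and pure shifts", {
  set.seed(5)
  r <- rnorm(64)
  # identical pair -> delta at lag 0
  s <- line_scan_series(rbind(r, r), cal, background_removed = TRUE)
  p <- make_delayed_pairs(fft_rows(s), 1)
  st <- phase_correlate(p$reference, p$delayed, 1)
  expect_identical(st$lag_axis[which.max(st$correlograms[1, ])], 0L)

  # +5 px shift (zero-fill) -> argmax at +5
  r2 <- c(rep(0, 5), r[1:59])
  s2 <- line_scan_series(rbind(r, r2), cal, background_removed = TRUE)
  p2 <- make_delayed_pairs(fft_rows(s2), 1)
  st2 <- phase_correlate(p2$reference, p2$delayed, 1)
  expect_identical(st2$lag_axis[which.max(st2$correlograms[1, ])], 5L)
  expect_error(phase_correlate(p2$reference, p2$delayed, 1, epsilon = -1),
               "epsilon")
})

test_that("plain correlation (alpha 0) matches the brute-force oracle", {
  set.seed(11)
  for (L in c(32, 64)) {
    a <- rnorm(L); b <- rnorm(L)
    s <- line_scan_series(rbind(a, b), cal, background_removed = TRUE)
    p <- make_delayed_pairs(fft_rows(s), 1)
    st <- phase_correlate(p$reference, p$delayed, phase_exponent = 0)
    bf <- brute_force_correlate(a, b)
    expect_equal(st$correlograms[1, ], bf$correlogram,
                 tolerance = 1e-6 * max(abs(bf$correlogram)))
  }
})

test_that("antisymmetry: swapping reference and delayed negates the shift", {
  sim <- render_linescans(constant_scene(6.5, 70, Inf, 0.05, seed = 21))
  ser <- subtract_background(sim$series)
  F <- fft_rows(ser)
  p <- make_delayed_pairs(F, 1)
  fwd <- normalize_to_probability(phase_correlate(p$reference, p$delayed, 1))
  rev <- normalize_to_probability(phase_correlate(p$delayed, p$reference, 1))
  for (i in c(1, 40, 80)) {
    a <- fit_peak(fwd$correlograms[i, ], fwd$lag_axis)
    b <- fit_peak(rev$correlograms[i, ], rev$lag_axis)
    expect_equal(a$shift_px, -b$shift_px, tolerance = 0.05)
  }
})

test_that("frame averaging reduces off-peak noise by roughly sqrt(W)", {
  # i.i.d. noise correlograms with a fixed embedded peak
  set.seed(42)
  M <- 320; nl <- 127
  corr <- matrix(rnorm(M * nl, 0, 0.1), M, nl)
  corr[, 64] <- corr[, 64] + 5
  st <- structure(list(correlograms = corr, lag_axis = -63:63,
                       time_axis = seq_len(M) / 2600, normalized = FALSE,
                       delay_steps = 1L, n_space = 64L, calibration = cal),
                  class = "correlogram_stack")
  expect_identical(average_frames(st, 1), st)       # W = 1 is the identity
  av <- average_frames(st, 16)
  expect_identical(nrow(av$correlograms), 20L)
  off <- av$correlograms[, -(54:74)]
  ratio <- sd(off) / sd(corr[, -(54:74)])
  expect_lt(abs(ratio - 0.25), 0.25 * 0.25)         # 1/sqrt(16), +-25%
  expect_error(average_frames(st, 1000), "window")
})

test_that("frame averaging at 26 turns 2600 correlograms/s into 100 points/s", {
  sim <- render_linescans(constant_scene(10, 30, Inf, 1, seed = 2))
  tr <- piv_analyze(sim$series, analysis_config(
    delay_steps = 1, velocity_points_per_second = 100))
  # 2600 scans -> 2599 pairs -> floor(2599/26) = 99 velocity points
  expect_identical(nrow(tr), 99L)
  expect_equal(diff(tr$time_s)[1], 26 / 2600, tolerance = 1e-9)
})

test_that("probability normalization yields unit-mass non-negative rows", {
  corr <- rbind(c(rep(0, 5), 1, rep(0, 5)),   # delta stays a delta
                rep(3, 11),                    # constant row -> uniform
                rnorm(11))
  st <- structure(list(correlograms = corr, lag_axis = -5:5,
                       time_axis = 1:3, normalized = FALSE, delay_steps = 1L,
                       n_space = 6L, calibration = cal),
                  class = "correlogram_stack")
  out <- normalize_to_probability(st)
  expect_true(all(out$correlograms >= 0))
  expect_equal(rowSums(out$correlograms), rep(1, 3), tolerance = 1e-12)
  expect_equal(out$correlograms[1, ], c(rep(0, 5), 1, rep(0, 5)))
  expect_equal(out$correlograms[2, ], rep(1 / 11, 11))
  expect_error(normalize_to_probability(out), "already")
})

test_that("Gaussian peak fitting reaches sub-0.05 px accuracy", {
  lag <- -63:63
  for (c0 in c(-10.3, 0, 0.5, 10.3, 17.7)) {
    y <- 0.02 + exp(-(lag - c0)^2 / (2 * 2^2))
    f <- fit_peak(y, lag, 4)
    expect_false(f$failed)
    expect_lt(abs(f$shift_px - c0), 0.05)
    expect_gt(f$peak_quality, 0.9)
  }
  # symmetric peak centred exactly on a lag stays there
  y <- exp(-(lag - 7)^2 / 8)
  expect_equal(fit_peak(y, lag, 4)$shift_px, 7, tolerance = 1e-9)
})

test_that("flat rows and boundary peaks are flagged failures", {
  lag <- -40:40
  flat <- fit_peak(rep(1, 81), lag, 4)
  expect_true(flat$failed)
  expect_identical(flat$peak_quality, 0)
  edge <- exp(-(lag - 39)^2 / 2)   # argmax within w of the boundary
  f <- fit_peak(edge, lag, 4)
  expect_true(f$failed)
  expect_error(fit_peak(c(1, 2, 1), fit_halfwidth_px = 4), "shorter")
})

test_that("shift-to-velocity conversion implements v = dx/dt", {
  expect_identical(shift_to_velocity(0, cal, 1), 0)
  expect_equal(shift_to_velocity(1, cal, 1), 1.3)            # 0.5 um * 2600 Hz
  cal2 <- scan_calibration(0.4, 2600)
  expect_equal(shift_to_velocity(2, cal2, 5), 0.416)
  expect_equal(shift_to_velocity(-3, cal, 2), -1.95)         # signed
})

test_that("delay selection doubles until the displacement floor is met", {
  # fast flow: large shift at N = 1
  fast <- subtract_background(
    render_linescans(constant_scene(26, 140, Inf, 0.3, seed = 6))$series)
  expect_identical(select_delay(fast, analysis_config()), 1L)

  # slow capillary-like flow at 0.5 px/scan -> first doubling with
  # median shift >= 3 px is N = 8
  slow <- subtract_background(
    render_linescans(constant_scene(0.65, 50, Inf, 0.6, seed = 6))$series)
  expect_identical(select_delay(slow, analysis_config()), 8L)

  # zero flow: max delay with a warning
  still <- subtract_background(
    render_linescans(constant_scene(0, 50, Inf, 0.3, seed = 6))$series)
  expect_warning(N <- select_delay(still, analysis_config()), "slow or absent")
  expect_identical(N, 32L)
})

test_that("full pipeline recovers a constant 10 mm/s flow within 2%", {
  sim <- simulate_linescans(constant_scene(10, 140, 8, 1, seed = 42))
  tr <- piv_analyze(sim$series, analysis_config(delay_steps = 1))
  v <- mean(tr$velocity_mm_s[!tr$outlier_flag])
  expect_lt(abs(v - 10) / 10, 0.02)
  summ <- summarize_trace(tr)
  expect_gte(summ$peak_mm_s, summ$mean_mm_s)
})

test_that("identical input and config give bit-identical traces", {
  sc <- constant_scene(5, 60, 4, 0.3, seed = 17)
  a <- piv_analyze(simulate_linescans(sc)$series, analysis_config(delay_steps = 1))
  b <- piv_analyze(simulate_linescans(sc)$series, analysis_config(delay_steps = 1))
  expect_identical(a, b)
})
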