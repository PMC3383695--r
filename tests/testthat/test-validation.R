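test_that("brute-force correlation recovers identity and translations", {
  set.seed(1)
  a <- rnorm(32)
  self <- brute_force_correlate(a, a)
  expect_equal(self$best_shift, 0, tolerance = 0.01)

  b <- c(rep(0, 3), a[1:29])  # +3 px with zero fill
  sh <- brute_force_correlate(a, b)
  expect_equal(sh$best_shift, 3, tolerance = 0.01)

  expect_error(brute_force_correlate(a, a[1:10]), "equal length")
  expect_error(brute_force_correlate(1:3, 1:3), "length >= 4")
})

test_that("argument swap reverses the brute-force lag axis", {
  set.seed(2)
  a <- rnorm(24); b <- rnorm(24)
  ab <- brute_force_correlate(a, b)
  ba <- brute_force_correlate(b, a)
  expect_equal(ab$correlogram, rev(ba$correlogram), tolerance = 1e-12)
})

test_that("accuracy scoring reproduces closed-form cases", {
  t <- seq(0, 1, length.out = 200)
  v <- seq(1, 100, length.out = 200)
  truth <- velocity_trace(t, v)

  perfect <- score_accuracy(velocity_trace(t, v), truth)
  expect_identical(perfect$median_rel_error_pct, 0)
  expect_equal(perfect$max_speed_within_tol_mm_s, 100)
  expect_identical(perfect$outlier_rate_pct, 0)

  biased <- score_accuracy(velocity_trace(t, 1.03 * v), truth)
  expect_equal(biased$median_rel_error_pct, 3, tolerance = 1e-9)
  expect_equal(biased$max_speed_within_tol_mm_s, 100)
  expect_gte(biased$p95_rel_error_pct, biased$median_rel_error_pct)

  # beyond tolerance everywhere: no bin passes
  off <- score_accuracy(velocity_trace(t, 1.2 * v), truth)
  expect_true(is.na(off$max_speed_within_tol_mm_s))

  flagged <- velocity_trace(t, v, outlier_flag = rep(TRUE, 200))
  expect_error(score_accuracy(flagged, truth), "no unflagged")
  expect_error(score_accuracy(truth, flagged), "no flagged points")
})

test_that("scoring medians are invariant under point reordering", {
  set.seed(4)
  t <- seq(0, 1, length.out = 100)
  v <- 50 + 10 * sin(2 * pi * t)
  est <- v * (1 + rnorm(100, 0, 0.02))
  r1 <- score_accuracy(velocity_trace(t, est), velocity_trace(t, v))
  perm <- sample(100)
  r2 <- score_accuracy(velocity_trace(t[perm], est[perm]),
                       velocity_trace(t, v))
  expect_equal(r1$median_rel_error_pct, r2$median_rel_error_pct,
               tolerance = 1e-9)
})

test_that("v_floor keeps relative error finite near flow reversal", {
  t <- seq(0, 1, length.out = 50)
  truth <- velocity_trace(t, seq(-0.2, 0.2, length.out = 50))
  est <- velocity_trace(t, seq(-0.2, 0.2, length.out = 50) + 0.1)
  r <- score_accuracy(est, truth)
  # |err| = 0.1 against floor 0.5 -> 20%, never a blow-up
  expect_equal(r$median_rel_error_pct, 20, tolerance = 1e-6)
})

test_that("analyze agrees with a brute-force oracle trace on clean data", {
  # ramp (not constant) flow so the trace sd in the denominator of the
  # discrepancy metric is physically meaningful
  wf <- make_waveform(2, 10, duration_s = 0.5, modulation_depth = 0)
  sim <- render_linescans(synthetic_scene(wf, roi_length_um = 70,
                                          target_snr = Inf, seed = 12))
  # plain-correlation configuration on both paths: the FFT pipeline must
  # reproduce the direct O(L^2) computation through the whole trace
  tr <- piv_analyze(sim$series, analysis_config(
    delay_steps = 1, phase_exponent = 0, symmetric_pairing = FALSE,
    edge_guard_px = 0, min_peak_psr = 0))
  # oracle: brute-force correlograms of raw background-subtracted row pairs,
  # averaged over the same 26-frame windows, then the shared sub-pixel fit
  ser <- subtract_background(sim$series)
  m <- ser$data
  W <- 26L
  lags <- seq.int(-(ncol(m) - 1L), ncol(m) - 1L)
  n_g <- (nrow(m) - 1L) %/% W
  oracle_v <- vapply(seq_len(n_g), function(g) {
    rows <- ((g - 1L) * W + 1L):(g * W)
    cc <- Reduce(`+`, lapply(rows, function(i)
      brute_force_correlate(m[i, ], m[i + 1L, ])$correlogram)) / W
    shift_to_velocity(fit_peak(cc, lags, 4)$shift_px,
                      sim$series$calibration, 1L)
  }, 0)
  oracle <- velocity_trace(tr$time_s[seq_len(n_g)], oracle_v)
  expect_lt(compare_traces(tr, oracle), 1)
})
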