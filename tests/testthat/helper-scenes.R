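# Shared scene builders: the study conditions exercised throughout the suite.
# 2.6 kHz line rate and 0.5 um/px mirror a typical two-photon line-scan setup.

default_cal <- function() scan_calibration(0.5, 2600)

# Linear speed ramp with 10 Hz heartbeat-like modulation.
ramp_scene <- function(top_speed_mm_s, roi_um, snr, duration_s, seed,
                       depth = 0.2) {
  wf <- make_waveform(0, top_speed_mm_s, duration_s = duration_s,
                      modulation_freq = 10, modulation_depth = depth)
  synthetic_scene(wf, roi_length_um = roi_um, duration_s = duration_s,
                  target_snr = snr, seed = seed)
}

constant_scene <- function(speed_mm_s, roi_um, snr, duration_s, seed,
                           depth = 0) {
  wf <- make_waveform(speed_mm_s, speed_mm_s, duration_s = duration_s,
                      modulation_depth = depth)
  synthetic_scene(wf, roi_length_um = roi_um, duration_s = duration_s,
                  target_snr = snr, seed = seed)
}

# Flow that reverses twice: +15 -> -15 -> +15 mm/s over the duration,
# modulated at 10 Hz. True zero crossings at duration/4 and 3*duration/4.
reversal_scene <- function(snr, duration_s, seed, roi_um = 50) {
  wf <- make_waveform(0, 0, duration_s = duration_s, modulation_freq = 10,
                      modulation_depth = 0.2,
                      base_times = c(0, duration_s / 2, duration_s),
                      base_values = c(15, -15, 15))
  synthetic_scene(wf, roi_length_um = roi_um, duration_s = duration_s,
                  target_snr = snr, seed = seed)
}

# Background-subtracted series wrapper for operator-level tests.
as_subtracted <- function(mat, cal = default_cal()) {
  subtract_background(line_scan_series(mat, cal))
}
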