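# lspiv — line-scanning particle image velocimetry for blood-flow kymographs

Two-photon and confocal microscopes can sweep a single scan line along a
blood vessel thousands of times per second. Stacking the sweeps gives a
space-time image in which red blood cells — dark against fluorescently
labelled plasma — advance from row to row. Classic streak-angle analysis of
such kymographs fails once cells move more than a cell diameter between
scans, capping measurable speeds far below what arteries and high-flow
lesions (such as arteriovenous malformations) actually carry.

`lspiv` recovers velocity from the *displacement of the particle ensemble*
between a scan and its Nth successor instead. Each delayed scan pair is
cross-correlated in the Fourier domain under a symmetric phase-weighted
filter

&nbsp;&nbsp;&nbsp;&nbsp;G(k) = conj(S₁(k))·S₂(k) / (|S₁(k)||S₂(k)| + ε)^α,

the correlation peak is fitted with a Gaussian for sub-pixel displacement
d̂, and velocity follows from the scan calibration:

&nbsp;&nbsp;&nbsp;&nbsp;v = Δx/Δt = d̂ · pixel_size · line_rate / N  (mm/s).

Slow capillary flow (fractions of a pixel per scan) is resolved by
automatically increasing the pair delay N; fast flow (hundreds of mm/s) by
long regions of interest with linear, zero-padded correlation. The package
bundles:

* the full analysis pipeline (`piv_analyze()`) with background subtraction,
  ROI cropping, automatic delay selection, frame averaging, Gaussian
  sub-pixel peak fitting, and two quality-control flags (running-window
  outliers and peak-to-sidelobe detection failures);
* a synthetic line-scan simulator (`synthetic_scene()`,
  `simulate_linescans()`) with exact ground truth: randomized 1–7 µm
  particles, ramp/pulsatile/reversing velocity waveforms, SNR-calibrated
  Gaussian noise;
* implementation-independent oracles (`brute_force_correlate()`) and
  accuracy scoring against ground truth (`score_accuracy()`);
* TIFF/CSV line-scan I/O and a command-line workflow
  (`exec/lspiv analyze | simulate | validate`).

Intended users: microscopists and hemodynamics researchers analysing
line-scan velocimetry data, and method developers who need a controlled
simulation bench for kymograph velocimetry.

## Worked example

Simulate a pulsatile arterial segment and analyse it blind:

```r
library(lspiv)

wf    <- make_waveform(10, 40, duration_s = 2,
                       modulation_freq = 10, modulation_depth = 0.2)
scene <- synthetic_scene(wf, roi_length_um = 140, duration_s = 2,
                         target_snr = 8, seed = 7)
sim   <- simulate_linescans(scene)

trace <- piv_analyze(sim$series, analysis_config(delay_steps = 1))
trace
#> <velocity_trace> 199 points over 1.980 s, 0 flagged
#>   velocity (unflagged): mean 24.847, range [8.948, 46.446] mm/s

summarize_trace(trace)
#> <trace_summary> mean 24.847 mm/s, peak 46.446, trough 8.948,
#>                 pulsatility 1.509 (199 points, 0 outliers)

score_accuracy(trace, sim$truth)
#> <accuracy_report> median err 0.35%, p95 0.813%, accurate to 46.65 mm/s
#>                   (<= 5%), outliers 0%, n = 199
```

The scene ramps from 10 to 40 mm/s with a 10 Hz heartbeat-like modulation
(hence the mean of ~25 mm/s, the 46 mm/s systolic peak, and pulsatility
(peak − trough)/mean ≈ 1.5). At SNR 8 the recovered trace tracks the ground
truth with a median relative error of 0.35%, and every speed bin up to the
scene's maximum stays within the 5% tolerance.

The same run from the shell:

```sh
exec/lspiv simulate --output-tiff scan.tif --output-truth truth.csv \
    --base-start 10 --base-end 40 --duration-s 2 --snr 8 --seed 7
exec/lspiv analyze  --input scan.tif --output trace.csv \
    --pixel-size-um 0.5 --line-rate-hz 2600 --delay-steps 1
exec/lspiv validate --trace trace.csv --truth truth.csv --output metrics.json
```

## Method notes

See the methods vignette (`vignettes/lspiv-methods.Rmd`) for the model and
its assumptions, the reasoning behind the window edge guard, symmetric
pairing and the spectral low-pass in the phase filter, the operational SNR
definition, simulator design choices, and known limitations (component of
velocity along the scan line only; very short capillary windows; no optical
PSF or motion-artifact modelling).
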