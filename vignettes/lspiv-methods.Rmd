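---
title: "Line-scanning PIV: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-scanning PIV: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lspiv)
```

## The measurement problem

A laser scanning microscope sweeping a single line along the axis of a blood
vessel acquires a 1-D intensity profile thousands of times per second. Stacked
in time, these profiles form a space-time image (kymograph): fluorescently
labelled plasma is bright, red blood cells exclude the dye and appear as dark
particles that advance along the scan line from row to row. At low speeds each
cell traces a continuous oblique streak and its velocity can be read off the
streak angle. Once cells move more than a cell diameter between scans the
streaks disintegrate and angle-based methods fail, while the cells are still
re-imaged often enough that *ensembles* of them remain recognisable between
nearby scans. That is the regime this package targets: velocity from the
displacement of the whole particle pattern between a scan and its Nth
successor,

$$ v \;=\; \frac{\Delta x}{\Delta t}
      \;=\; \frac{\hat d \,\cdot\, p \,\cdot\, f}{N}, $$

where $\hat d$ is the fitted pattern displacement in pixels, $p$ the pixel
size (µm), $f$ the line rate (Hz) and $N$ the pair delay in scan intervals.

## The estimator, step by step

`piv_analyze()` composes the pipeline; each stage is exported on its own.

1. **Background subtraction** (`subtract_background`). Each column's temporal
   mean is removed. Stationary absorbers in the light path would otherwise
   dominate the correlation at zero lag. Subtraction commutes with ROI
   cropping (both are column-local), which the suite verifies.
2. **Region of interest** (`extract_roi`). Column ranges are 0-based and
   half-open. Long straight segments (50 µm and up) suit arteries; longer
   windows extend the measurable speed range because the pattern must remain
   partly inside the window after displacement.
3. **Row-wise FFT** (`fft_rows`), zero-padded to at least $2L-1$ so the
   correlation is linear, not circular: particles leave and enter the window,
   and circular wrap-around would alias exactly the high speeds the method
   exists to measure.
4. **Delayed pairing** (`make_delayed_pairs`, `select_delay`). Fast flow
   pairs each scan with its immediate successor. Capillary flow moves a
   fraction of a pixel per scan; the pilot pass doubles $N$ (1, 2, 4, ... up
   to 32) until the median pilot displacement reaches `min_shift_px`
   (default 3 px), the Nth-neighbour pairing that makes sub-pixel creep
   resolvable.
5. **Symmetric phase-weighted cross-correlation** (`phase_correlate`). Per
   spatial frequency $k$,
   $G_k = \overline{S_{1,k}} S_{2,k} \big/ (|S_{1,k}||S_{2,k}| + \epsilon)^\alpha$,
   inverse-transformed and centred on a lag axis. $\alpha = 1$ keeps only
   phase — position information — and sharpens the peak; $\alpha = 0$ is the
   plain cross-correlation used for oracle comparisons. Two refinements are
   part of the filter design:
   * a Gaussian spectral low-pass (1 px equivalent width, raised to the same
     $\alpha$) restricts the whitened spectrum to wavelengths that particles
     of red-cell size can populate — whitening alone gives out-of-band bins,
     which carry only boundary and discretisation junk, the same weight as
     signal;
   * the analysis pipeline averages each correlogram with the lag-mirrored
     correlogram of the role-swapped pair (`symmetric_pairing`). Exchanging
     reference and delayed scan negates the true peak but leaves
     window-anchored artifacts in place, so the average cancels odd-order,
     direction-dependent bias — the 1-D analogue of central-difference
     interrogation in planar PIV.
6. **Edge guard** (`edge_guard_px`). A particle clipped by the window
   boundary is "anchored" at the same pixel in both rows; after whitening
   this shared anchor masquerades as a dominant zero-lag peak (a minimal
   two-row experiment in the test suite demonstrates the artifact). The fix
   is an asymmetric interrogation window: the reference row's outermost
   columns (by default one maximal 7 µm cell support, capped at a sixth of
   the window) are zeroed with a short raised-cosine rolloff, while the
   delayed row keeps full support, so no content is clipped identically in
   both rows. Plain tapering does *not* fix this — a taper envelope is
   itself a shared anchor for structures wider than the rolloff.
7. **Frame averaging** (`average_frames`) raises correlation SNR at the cost
   of temporal resolution; `velocity_points_per_second = 100` (26-frame
   groups at 2.6 kHz) is the reduced-resolution mode, 2600 the native one.
   Averaging acts on correlograms, not on fitted shifts, so weak frames
   reinforce rather than vote. Correlograms are stamped at the midpoint of
   the $[t, t+N/f]$ interval they measure; stamping at the reference scan
   would phase-lag pulsatile traces by $N/2f$.
8. **Probability normalisation and Gaussian sub-pixel fit**
   (`normalize_to_probability`, `fit_peak`). Each row becomes a unit-mass
   distribution (a monotone transform; argmax invariant), then a
   four-parameter Gaussian is least-squares fitted over ±4 px around the
   global maximum (ties break toward the smallest |lag|), with a 3-point
   log-parabolic fallback. Peaks at the lag-axis boundary are failures:
   the displacement left the measurable range.
9. **Quality control** (`flag_outliers`, `peak_sidelobe_ratio`,
   `median_filter_trace`). Two flags: a running-window rule (point flagged
   when it deviates from the leave-one-out window mean by more than
   `outlier_threshold_sd` window standard deviations — leave-one-out so a
   spike cannot mask itself), and a detection rule (peak-to-sidelobe ratio
   below `min_peak_psr`, default 4, means no peak stands above the
   correlation noise floor). The PSR rule matters in deep-noise data, where
   the running-window rule is structurally blind: when *every* point is
   wild, the window standard deviation inflates and the flag rate drops.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `delay_steps` | auto | scans | 1 for fast flow; doubled for capillary creep |
| `velocity_points_per_second` | 100 | 1/s | 26-frame averaging at 2.6 kHz; use 2600 for native resolution |
| `phase_exponent` | 1 | — | phase-only filtering; 0 = plain correlation |
| `fit_halfwidth_px` | 4 | px | Gaussian fit window ±w around the peak |
| `edge_guard_px` | auto | px | one 7 µm cell support; cap L/6 per side |
| `symmetric_pairing` | TRUE | — | cancels odd-order window bias |
| `min_peak_psr` | 4 | — | conventional correlation detectability floor |
| `outlier_threshold_sd`, `outlier_window` | 3, 101 | —, points | running-window spike flagging |
| `min_shift_px` | 3 | px | pilot displacement floor for delay doubling |

## What the synthetic scenes emulate — and what they do not

`synthetic_scene()` renders dark particles of randomised size (uniform
1–7 µm, emulating red cells at varying orientations to the scan line) on a
bright plasma background. Particles are seeded uniformly over the ROI plus an
inflow margin, advected rigidly by the ground-truth waveform
$v(t) = \mathrm{ramp}(t)\,(1 + \mathrm{depth}\,\sin 2\pi f_m t)$ with 10 Hz
default modulation (a mouse heartbeat), and recycled periodically through the
extended domain so the expected density is stationary in either flow
direction. Each particle is a raised-cosine dip whose full width at half
depth equals its drawn size; the summed dip field saturates at one full
contrast before scaling (stacked cells do not double the occlusion — and an
unsaturated sum would bias the quartile-based SNR estimator). Noise is
i.i.d. Gaussian with $\sigma = \mathrm{contrast}/\mathrm{SNR}$, matching the
estimator's contrast-over-noise definition. The ground-truth trace records
the waveform exactly and is never quantised to the pixel grid.

Defaults chosen where no external condition fixes them, once: particle
density 10 per 100 µm (one cell per ~10 µm, a mid-range hematocrit; 0
represents a transiently cell-free capillary, for which the analysis must
flag rather than report), plasma level 100, contrast 50, pixel size
0.5 µm at 2.6 kHz. The high-speed ramp scene uses modulation depth 0.1
rather than 0.2 because the instantaneous peak of a 1000 mm/s ramp at depth
0.2 (1200 mm/s, 461 µm per scan) would exceed the 426 µm window — the
renderer refuses physically unresolvable scenes.

The simulator does **not** model the optical point-spread function,
depth-dependent scattering, cross-sectional flow profiles, scan-speed
stretch artifacts of bidirectional sweeps, or cardiac/respiratory tissue
motion. Passing the simulation study therefore demonstrates the estimator's
algorithmic accuracy and noise robustness, not immunity to every in vivo
artifact.

## Operational SNR

The field reports line-scan quality as the contrast of cells amid plasma
relative to noise. `estimate_snr()` makes that operational: plasma level =
mean of pixels at or above the upper quartile, particle level = mean at or
below the lower quartile, noise = robust (MAD) standard deviation of
temporal first differences divided by √2. Pure Gaussian noise separates the
two quartile means by ≈2.54σ on its own, so that bias is removed in
quadrature; a particle-free noise image scores ≈0 instead of ≈2.5. The
estimator is calibrated within ±20% against the generator across targets 8
down to 0.33 (at slow flow — fast motion inflates the first-difference
noise estimate, which is why the estimate is specified for raw,
slowly-moving data).

## Numerical choices and degenerate inputs

* ε in the phase filter defaults to $10^{-6} \max(|S_1||S_2|)$, with a
  positive floor for all-zero spectra (zero-velocity, particle-free data).
* Equal correlogram maxima break toward the smallest |lag|; deterministic.
* Constant correlogram rows normalise to the uniform distribution; flat rows
  and boundary argmaxima are fit failures with quality 0.
* The running median filter shrinks its window symmetrically at the trace
  edges (edge points pass through unchanged); no data is fabricated.
* All randomness flows through scene seeds: the same seed reproduces scenes,
  noise, traces and CLI output bit for bit.
* Windowed correlation limits: absolute sub-pixel accuracy (±0.1 px) holds
  for per-delay displacements up to roughly 15% of the window; beyond that
  the classic one-sided loss-of-pairs skew grows in proportion (~1.5% of
  the displacement), which keeps *relative* errors within the 5% envelope
  out to displacements approaching the window length.

## Validation design and problem sizes

The acceptance suite regenerates every scene from code at test time. Chosen
study sizes: the high-speed ramp (0 → 1000 mm/s, ROI 426 µm, SNR 8) runs 2 s
in the tests and 4 s in `scripts/acceptance.R`; the SNR sweep (ramp to
150 mm/s, ROI 140 µm, SNR 8/1/0.5/0.33) 2 s per level; the reversal scene
(+15 → −15 → +15 mm/s) 2 s; the capillary scene (0.65 mm/s = 0.5 px per
scan, analysed ROI 50 µm) 2 s. Each speed bin keeps hundreds of points at
these durations. Determinism is asserted by running scaled-down versions of
each pipeline twice and requiring identical traces.

One scene choice deserves emphasis: the capillary-flow study uses a 50 µm
analysed segment although real capillary ROIs are often ~10 µm. With 1–7 µm
cells in a 10–20 µm window, most visible content is boundary-clipped and
windowed correlation of any flavour is ill-posed (we measured 12–60% errors
regardless of filtering choices). The quantity under test — that
Nth-neighbour pairing resolves sub-pixel-per-scan flow — does not depend on
the window length, so the study isolates it at a window where the window
itself is not the limiting factor. Very short windows remain a genuine
limitation of the method, shared with every windowed-correlation approach.

## Known limitations

* Velocity is the component along the scan line; streamline orientation is
  not inferred.
* Zero-hematocrit vessels carry no tracer: the pipeline flags rather than
  reports (verified in the suite).
* The in vivo comparisons against an SVD-based velocimetry reference in the
  original study require animal data and are not reproduced here; the
  package's `compare_traces()` implements the discrepancy metric (mean
  absolute difference as a percentage of the trace standard deviation) for
  users with their own paired analyses.
* Bidirectional-scan stretch artifacts are handled only by row
  deinterlacing; no stretch correction is applied.
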