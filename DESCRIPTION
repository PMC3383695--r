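Package: lspiv
Title: Line-Scanning Particle Image Velocimetry for Blood-Flow Kymographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Recovers time-resolved red-blood-cell velocities from line-scan
    (space-time / kymograph) microscopy data by delayed-pair Fourier
    cross-correlation with symmetric phase-weighted filtering and Gaussian
    sub-pixel peak fitting. Includes preprocessing (background subtraction,
    region-of-interest cropping, signal-to-noise estimation), automatic
    delay selection for slow capillary flow, outlier flagging and median
    filtering of velocity traces, a synthetic line-scan simulator with
    ground-truth velocity waveforms and calibrated noise, brute-force
    correlation oracles for validation, and a command-line interface for
    the analyze / simulate / validate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
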