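Package: ppgkit
Title: Photoplethysmography Beat Detection, Vital Signs and Device Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for wrist-worn photoplethysmography (PPG)
    recordings: harmonic-to-noise-ratio signal qualification by the Boersma
    autocorrelation method, wavelet-transform beat detection with sub-sample
    onset refinement, robust interbeat-interval filtering, per-window heart
    rate, SDNN/RMSSD heart-rate variability and respiration rate (fused
    baseline-wander and frequency-modulation estimators), and the
    method-comparison statistics used to benchmark such devices (Pearson
    correlation, repeated-measures Bland-Altman limits of agreement,
    window-duration sensitivity). Includes a synthetic PPG generator with
    retained ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
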