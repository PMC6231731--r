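# ppgkit

Processing chain for wrist-worn photoplethysmography (PPG)
recordings, for engineers and researchers validating wearable
vital-sign devices. From a raw optical waveform (nominally 86 Hz) and
an optional 10 Hz motion trace, the package derives per-window resting
heart rate, time-domain heart-rate variability and respiration rate,
and provides the method-comparison statistics used to benchmark those
estimates against reference devices (ECG, spirometry).

The stages:

* **Signal qualification** — harmonic-to-noise ratio (HNR) by
  Boersma's autocorrelation method on 6-s windows centered 1 s apart:
  `HNR = 10·log10(r*/(1−r*))` dB, where `r*` is the peak of the
  taper-corrected normalized autocorrelation over heart-period lags.
  Recordings below an HNR threshold, or with an elevated motion
  envelope, are excluded from vital-sign analysis.
* **Beat segmentation** — Ricker continuous-wavelet-transform peak
  detection, greedy systolic-apex selection under interbeat-interval
  constraints, sub-sample parabolic refinement, and per-beat
  qualification by template correlation, short-time spectral content
  and motion overlap.
* **Vitals** — ectopic-interval removal (log-IBI more than 6.25
  median absolute deviations from the full-recording median),
  `HR = 60000/mean(IBI)`, SDNN (sample SD), RMSSD
  (`sqrt(mean(diff(IBI)²))`), and respiration rate fusing a
  baseline-wander cycle count with a Morlet-CWT ridge traced through
  the frequency-modulated heart-period series.
* **Validation** — MAE/MAPE/ME, Pearson correlation, Bland–Altman
  limits of agreement with the repeated-measures variance-components
  correction (`sd² = MSW + (MSB−MSW)/n0`), the Bland–Altman ratio,
  left/right agreement, and 60/45/30-s window-duration sensitivity.
* **Synthetic ground truth** — a generator that renders pulsatile PPG
  (systolic + dicrotic Gaussian complexes) with respiratory baseline
  wander, amplitude modulation, RSA frequency modulation, white noise
  and motion-artifact transients, retaining true beat times and
  per-window truth metrics for parameter-recovery testing.

See `vignettes/ppg-pipeline.Rmd` for the full methods account.

## Worked example

Simulate a 3-minute session with known physiology, run the pipeline,
and compare against truth:

```r
library(ppgkit)

s <- simulate_session(
  hrv  = hrv_params(hr_mean_bpm = 72, jitter_sd_ms = 35),
  resp = resp_modulation_params(rr_brpm = 14),
  duration_s = 180, noise_sd = 0.15, seed = 42)

wm <- compute_window_metrics(s$ppg)
round(as.data.frame(wm)[, c("window_start_s", "hr_bpm", "sdnn_ms",
                            "rmssd_ms", "rr_brpm", "hnr_db", "n_beats")], 2)
#>   window_start_s hr_bpm sdnn_ms rmssd_ms rr_brpm hnr_db n_beats
#> 1              0  71.96   52.17    64.63   13.74  10.10      72
#> 2             60  72.33   45.50    56.76   13.70  10.87      72
#> 3            120  72.26   45.60    61.87   13.89  10.82      71

round(s$truth$window_truth[, c("start", "hr_bpm", "sdnn_ms",
                               "rmssd_ms", "rr_brpm")], 2)
#>   start hr_bpm sdnn_ms rmssd_ms rr_brpm
#> 1     0  71.95   51.57    64.65      14
#> 2    60  72.35   45.29    55.42      14
#> 3   120  72.27   45.27    59.99      14
```

Each row is one 60-second measurement: at pulse SNR ~10 the heart
rate is recovered to within a few hundredths of a bpm, SDNN/RMSSD to
a few ms, and the respiration rate to ~0.3 breaths/min; `hnr_db` is
the window's signal-quality index (about 10 dB here, comfortably
above the 3 dB qualification threshold), and `n_beats` the qualified
beat count. Agreement statistics work on any paired table:

```r
pairs <- data.frame(test = wm$hr_bpm,
                    ref = s$truth$window_truth$hr_bpm, subject = 1)
bland_altman(pairs)
#> <bland_altman: bias -0.010 (95% CI -0.041..0.021), LoA [-0.034, 0.015],
#>  ratio 0.000, n = 3 pairs / 1 subjects>
```

A command-line front end over the same functions ships in
`inst/cli/ppgkit.R` with `simulate`, `quality`, `vitals`, `validate`
and `run-all` subcommands.

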