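---
title: "From raw PPG to validated vital signs: the methods behind ppgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw PPG to validated vital signs: the methods behind ppgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgkit)
```

## The problem

A wrist-worn photoplethysmography (PPG) sensor measures blood-volume
changes in the microvascular bed under the skin. From that single
optical trace one can estimate resting heart rate (HR), time-domain
heart-rate variability (SDNN and RMSSD over the normal-to-normal
interbeat intervals) and respiration rate (RR). The catch is that
wrist PPG is fragile: perfusion is weaker than at the finger, subtle
arm movements corrupt whole segments, and respiration itself leaks
into the waveform through three mechanisms — baseline wander (tissue
blood volume), amplitude modulation (stroke volume) and frequency
modulation of the heart period (respiratory sinus arrhythmia, RSA).
A usable pipeline therefore needs, in order: signal qualification,
artifact gating, beat segmentation with sub-sample timing, robust
interval statistics, and respiration estimators that exploit — rather
than suffer from — the respiratory imprints. `ppgkit` implements that
chain and the method-comparison statistics used to benchmark such a
device against ECG and spirometry references.

## Signal qualification: harmonic-to-noise ratio

The periodicity of a PPG window is summarized by the
harmonic-to-noise ratio computed with Boersma's autocorrelation
method. The mean-removed, band-limited signal is tapered with a Hann
window; its normalized autocorrelation is divided by the window's own
normalized autocorrelation (removing the taper-induced lag bias); the
peak `r*` over lags 0.33–2.0 s (heart periods of 30–180 bpm) is
sharpened by parabolic interpolation; and

```
HNR = 10 log10( r* / (1 - r*) )   [dB]
```

clipped to [-20, +40] dB so the `r* -> 1` singularity stays finite.
For a sinusoid of power `P` in white noise of variance `s2`,
`r*` approaches `P / (P + s2)`, so HNR estimates `10 log10(P/s2)` —
the property the test suite checks over an SNR grid.

HNR is computed for 6-second windows whose centers are 1 second
apart, starting at 3 s so every window fits entirely (a 60-s
measurement yields exactly 55 windows), and the window mean is the
recording's HNR. A 60-s measurement qualifies for vital-sign analysis
when its mean HNR reaches `hnr_threshold_db` (default 3 dB — the
existence of the threshold is part of the method, its value is a
device-calibration choice) and its motion envelope (95th percentile
of |magnitude − median| over the window) stays below
`motion_threshold`.

Because HNR treats everything aperiodic as noise, respiratory
components must be removed first. The cardiovascular bandpass
(0.3–10 Hz) is realized as zero-phase Butterworth stages: two
cascaded 4th-order high-pass passes and one 4th-order low-pass, each
run forward and backward over a reflection-padded signal. Cascading
low-order stages keeps the filter numerically well conditioned at a
0.3 Hz corner on an 86 Hz grid, and the resulting 16th-order-magnitude
low edge is steep enough that a breathing component sitting just below
the band (e.g. 0.25 Hz) no longer moves HNR appreciably — with a
single 4th-order edge the leaked residual was measurable. Zero phase
matters because interbeat intervals are read off the filtered signal.

## Beat segmentation

Candidate peaks come from a Ricker (Mexican-hat) continuous wavelet
transform averaged over 8 logarithmic scales spanning pulse widths
0.06–0.18 s; local maxima of the averaged coefficient trace are
candidates. Systolic apices are then selected greedily by descending
CWT prominence under the constraint that no two selected beats are
closer than `min_ibi_s` (0.33 s); ties break on prominence, then
earlier time, making the selection independent of candidate discovery
order. A window whose dominant periodogram frequency falls outside
the admissible heart-rate band is marked unreliable.

Timing is refined in two stages: each selected candidate is snapped
to the nearest maximum of a single-scale Ricker trace (width 0.10 s),
and a least-squares parabola through ±2 samples gives the sub-sample
apex. The matched-filter character of the single-scale trace
suppresses in-band noise (timing jitter of a few ms at pulse SNR 10),
while the Ricker's negative side lobes cancel the pull the dicrotic
bump would otherwise exert on the apex — a plain Gaussian smoother
shifted apices by 2–3 samples on the same signals.

Beat timing, and hence the IBI series, is **apex-to-apex**. For
smooth pulses the inter-beat valley sits between the surrounding
apices, so valley-to-valley intervals behave like a moving average of
the true intervals and systematically understate short-term
variability; the apex is the sharper, better-localized fiducial. The
preceding valley is still located and reported per beat as the
systolic-onset feature, giving beat amplitude and rise time.

Each beat is then qualified by three heuristics: (a) Pearson
correlation of its segment, resampled to a fixed 50-point grid, with
the pointwise-median beat template (threshold 0.8; the median makes
the template robust to single corrupted beats); (b) at least half of
the short-time spectral power over the beat's own support must lie in
0.5–3.0 Hz — the support restriction keeps one corrupted beat from
contaminating its neighbors' checks; and (c) no motion-envelope
excursion may overlap the beat's support. An IBI enters downstream
statistics only when both bounding beats qualify and the interval
lies in [0.33, 2.0] s, so detection gaps never produce spurious long
intervals. Note that a strong artifact also has a footprint in the
*filtered* signal about 1–2 s beyond its nominal extent (the
zero-phase high-pass spreads energy symmetrically in time), so beats
immediately adjacent to an artifact may legitimately fail
qualification as well.

## Per-window vitals

Ectopic and otherwise non-normal intervals are removed without
replacement when the logarithm of an IBI lies more than 6.25 (unscaled)
median absolute deviations from the median log-IBI of the **full
recording**; recording-level statistics are applied per window, so a
window dominated by ectopy cannot recalibrate its own threshold. When
the MAD is zero (degenerate, e.g. perfectly constant intervals) the
rule falls back to an absolute log-deviation threshold of log(1.5)
and flags the result. The filter is idempotent.

With the surviving intervals of a window:

* `HR = 60000 / mean(IBI_ms)` (bpm),
* `SDNN` = sample standard deviation (n−1; a population variant is
  available),
* `RMSSD = sqrt(mean(diff(IBI)^2))` over adjacent qualified pairs.

HR and HRV require at least 30 qualified beats per 60 s (scaled
linearly for 45-s and 30-s windows) and at least half of the expected
beat count; otherwise the metric is absent, never an exception.

Respiration rate fuses two estimators, each with its own quality
score on [0, 1]:

* **Baseline wander** (time domain): the raw window is band-limited
  to 0.1–0.5 Hz (6–30 breaths/min, resting adults) and breath cycles
  are found with the same Ricker detector at breath-scale widths;
  RR = 60 / mean cycle length, quality = 1 − CV of the cycle lengths.
* **Frequency modulation** (frequency domain): the instantaneous HR
  series (one point per qualified IBI) is linearly interpolated onto
  a uniform 4 Hz grid, a complex Morlet transform (w0 = 5, so that
  0.1 Hz wavelets still fit a 60-s window) is evaluated over
  0.1–0.5 Hz, and the respiration ridge is the per-time power argmax;
  RR = 60 × median ridge frequency, quality = the fraction of
  time-averaged transform power within 0.05 Hz of the ridge.

Estimates with quality below 0.5 are discarded. If both survive and
agree within 4 breaths/min the quality-weighted mean is reported; if
they disagree the window reports no RR (disagreement signals that at
least one mechanism is not breathing-driven); a single survivor is
reported as is. Fused values cannot leave the analysis band.

## Validation statistics

Paired (device, reference) window measurements — kept only where both
sides are valid — feed: mean absolute error, mean absolute percentage
error and mean error with their sample SDs; Pearson correlation; and
Bland–Altman limits of agreement `bias ± 1.96 sd`. With repeated
windows per subject, `sd` comes from the variance-components
correction: a one-way ANOVA of the differences on subject gives
`sd^2 = MSW + (MSB − MSW)/n0` with
`n0 = (N − Σn_i²/N)/(m−1)`, describing the difference expected for a
new observation on a new individual rather than the narrower pooled
spread. The Bland–Altman ratio normalizes `1.96 sd` by the mean of
the pairwise means; the 95% CI on the bias uses a t quantile with
(subjects − 1) degrees of freedom. With one observation per subject
the repeated-measures form reduces exactly to the classic formula.
Test/reference beat series are aligned automatically by maximizing
the correlation of their IBI-versus-time step functions over a ±lag
grid at 0.25 s granularity — clock offset and pulse transit time are
absorbed into that one free parameter.

`window_sensitivity()` re-segments and fully re-analyzes recordings
at 60, 45 and 30 s, tabulating per-metric error against ground truth:
shorter windows multiply the number of measurements while the
minimum-beat requirements scale down with duration.
`bilateral_agreement()` pairs simultaneously recorded left/right
metrics by window.

## The synthetic generator, and what it does not emulate

`simulate_session()` draws an IBI series

```
ibi_k = mean_ibi (1 + fm_depth sin(2π f_resp t_k))
        + lf_amp sin(2π f_lf t_k) + ε_k ,   ε_k ~ N(0, jitter_sd²)
```

and renders one systolic + dicrotic Gaussian complex per beat,
multiplied by `(1 + am_depth sin(2π f_resp t))`, plus
`bw_depth sin(2π f_resp t)` baseline wander and white noise. The
truth beat time is the apex of the rendered complex (the dicrotic
bump pulls that apex slightly past the systolic Gaussian center, so
bump placement is compensated analytically). Motion artifacts are
unit-normalized random-walk transients with a matching elevated
segment in a 10 Hz motion trace; every random draw is governed by an
explicit seed argument and the global RNG state is never touched.
Per-window truth metrics apply the package's own estimator
definitions directly to the noiseless truth IBIs — shared definitions
without circularity, since truth never passes through detection.

`cohort_session()` fixes the study conditions used for
parameter-recovery validation: 70 sessions (35 virtual subjects × 2),
3 minutes each, HR 55–95 bpm, IBI jitter 15–55 ms, slow oscillation
5–25 ms, RSA depth 0.02–0.08, RR 8–20 breaths/min, baseline wander
0.3 and amplitude modulation 0.1 of pulse amplitude, analyzed
noise-free and at pulse-power SNR 10. The acceptance suite requires
the pipeline to beat, on this synthetic cohort, the error levels a
validated wristband achieves against ECG/spirometry in humans
(HR 0.7 bpm, SDNN 7 ms, RMSSD 11 ms, RR ~1 breath/min as MAE), with
roughly halved bounds on noise-free signals.

Deliberate simplifications, and hence what passing tests do *not*
show about real data: RSA is sinusoidal IBI modulation rather than
phase-coupled integral pulse frequency modulation; pulse morphology
is a fixed two-Gaussian complex with no beat-to-beat shape variation,
pulse-wave-velocity change or sensor-coupling drift; respiration is a
single stationary sinusoid per session; noise is white and Gaussian,
whereas real wrist PPG noise is colored and occasionally impulsive;
the motion model is a generic random walk, not a biomechanical
artifact; and skin tone, perfusion level and contact pressure — major
drivers of real signal quality — have no counterpart here. Recovery
errors on this cohort are therefore a lower bound on real-world
error, and the human-study error levels serve as upper bounds the
clean pipeline must beat, not as values to reproduce.

## Numerical choices and degenerate inputs

* Window boundaries are half-open with sample index `round(t·fs)`;
  an IBI belongs to the window containing its first beat.
* Trailing recording remainders shorter than one window are
  discarded; segmentation tolerates a 1e-9 relative duration epsilon
  so CSV-roundtripped recordings keep their last window.
* `filtfilt` is applied over ~10 s reflection padding; without it the
  0.3 Hz stage rings visibly at the edges.
* Autocorrelation and band-power computations zero-pad to a power of
  two; the beat-support spectrum is zero-padded 4× for stable band
  integration at one-beat segment lengths.
* Flat signals: error for HNR ("flat signal"), empty candidate list
  for detection.
* Fewer than 3 beats: no template can be formed, all beats
  unqualified. Boundary local maxima are returned unrefined and
  flagged.
* Waveform CSV ingestion rejects non-finite samples and any sampling
  step deviating more than 1 ppm (plus a 1 ns guard for printed
  precision) from the median step, naming the first offending row.

## Validation problem sizes

The acceptance suite analyzes the 70-session cohort twice (noise-free
and SNR 10) at 60-s windows (~210 window-metric pairs per metric per
arm), re-analyzes 20 sessions at 60/45/30 s, verifies the log-MAD
filter against a brute-force oracle on 200 randomized interval sets,
and checks the HNR estimator on 30 windows per SNR level. The whole
suite runs in a few minutes on one core; `scripts/acceptance.R`
repeats the cohort analysis end-to-end and writes the headline
numbers as JSON.

## Known limitations

* The HNR qualification threshold (3 dB) and the respiratory quality
  threshold (0.5) are assumptions, exposed in the configuration; the
  underlying product documentation states that thresholds exist but
  not their values.
* Gating is applied at the 60-s level; per-HNR-window gating inside a
  measurement is not attempted.
* The onset/apex convention is resolved in favor of apices for IBIs
  (see above); devices that report valley-to-valley intervals will
  differ slightly in RMSSD on strongly modulated signals.
* No frequency-domain HRV (LF/HF), no amplitude-modulation-only RR
  path, no SpO2: out of scope.
* `align_beats()` assumes a constant offset; clock drift over long
  recordings is not modelled.
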