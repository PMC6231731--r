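# Beat segmentation: wavelet-based candidate detection, onset selection
# under physiological interbeat-interval constraints, sub-sample apex
# refinement, and per-beat qualification by template correlation,
# short-time spectral content and motion overlap.

#' Beat detection configuration
#'
#' @param cwt_widths Ricker wavelet widths in seconds used for
#'   candidate detection; the default 8 logarithmic scales span pulse
#'   widths 0.06--0.18 s (systolic upstrokes over 30--180 bpm).
#' @param refine_width_s Ricker width of the single-scale trace used
#'   for sub-sample apex refinement. A near-matched scale suppresses
#'   in-band noise while its negative side lobes cancel the pull of the
#'   dicrotic bump on the apex location.
#' @param min_ibi_s,max_ibi_s admissible interbeat interval range in
#'   seconds (defaults 0.33 and 2.0, i.e. 30--180 bpm).
#' @param template_corr_min minimum Pearson correlation of a beat with
#'   the median beat template.
#' @param stft_band_hz frequency band (Hz) in which a qualified beat's
#'   short-time spectrum must concentrate at least half its power.
#' @param min_qualified_frac minimum fraction of expected beats per
#'   window that must qualify for the window to emit vitals.
#' @param motion_threshold per-beat motion envelope threshold.
#' @param cand_frac candidate peaks weaker than this fraction of the
#'   90th-percentile peak strength are dropped.
#' @param snap_radius samples searched around a candidate when snapping
#'   to the refinement-trace maximum.
#' @return List of class `beat_config`.
#' @export
beat_config <- function(cwt_widths = exp(seq(log(0.06), log(0.18),
                                             length.out = 8)),
                        refine_width_s = 0.10,
                        min_ibi_s = 0.33, max_ibi_s = 2.0,
                        template_corr_min = 0.8,
                        stft_band_hz = c(0.5, 3.0),
                        min_qualified_frac = 0.5,
                        motion_threshold = 0.5,
                        cand_frac = 0.2, snap_radius = 4L) {
  stopifnot(min_ibi_s < max_ibi_s, all(cwt_widths > 0))
  structure(list(cwt_widths = cwt_widths, refine_width_s = refine_width_s,
                 min_ibi_s = min_ibi_s, max_ibi_s = max_ibi_s,
                 template_corr_min = template_corr_min,
                 stft_band_hz = stft_band_hz,
                 min_qualified_frac = min_qualified_frac,
                 motion_threshold = motion_threshold,
                 cand_frac = cand_frac, snap_radius = snap_radius),
            class = "beat_config")
}

#' Wavelet-transform peak candidate detection
#'
#' Averages the Ricker continuous wavelet transform over the configured
#' scale range and returns the local maxima of the averaged coefficient
#' trace whose strength exceeds a small fraction of the typical peak
#' strength. On clean signals the candidates are a superset of the true
#' systolic apices; spurious candidates are pruned later by
#' [select_onsets()].
#'
#' @param w a band-limited `ppg_waveform`.
#' @param cfg a [beat_config()].
#' @return Integer vector of candidate sample indices with attribute
#'   `"strength"` (averaged CWT coefficient at each candidate). Empty
#'   for flat signals.
#' @export
detect_peaks_cwt <- function(w, cfg = beat_config()) {
  x <- w$values
  if (stats::sd(x) == 0) return(structure(integer(0), strength = numeric(0)))
  cw <- rowMeans(cwt_ricker(x, cfg$cwt_widths, w$fs))
  pk <- local_maxima(cw)
  pk <- pk[cw[pk] > 0]
  if (!length(pk)) return(structure(integer(0), strength = numeric(0)))
  thr <- cfg$cand_frac * stats::quantile(cw[pk], 0.9, names = FALSE)
  keep <- cw[pk] > thr
  structure(as.integer(pk[keep]), strength = cw[pk[keep]])
}

#' Select systolic apices from the candidate list
#'
#' Greedy selection by descending strength (prominence on the averaged
#' CWT trace), accepting a candidate only if it is at least
#' `min_ibi_s` from every already-accepted one — when two candidates
#' would violate the minimum interbeat interval, the stronger survives,
#' with earlier time as the deterministic tie break. The dominant
#' frequency of the window (periodogram peak of the band-limited
#' signal) must fall in the admissible heart-rate band; otherwise the
#' selection is marked unreliable.
#'
#' @param candidates integer indices from [detect_peaks_cwt()] (its
#'   `"strength"` attribute is used when present, otherwise strength is
#'   recomputed from the waveform).
#' @param w the `ppg_waveform` the candidates refer to.
#' @param cfg a [beat_config()].
#' @return Sorted integer vector of selected apex indices with logical
#'   attribute `"reliable"`.
#' @export
select_onsets <- function(candidates, w, cfg = beat_config()) {
  if (!length(candidates))
    return(structure(integer(0), reliable = FALSE))
  strength <- attr(candidates, "strength")
  if (is.null(strength)) strength <- w$values[candidates]
  ord <- order(-strength, candidates)
  cand <- candidates[ord]
  min_gap <- cfg$min_ibi_s * w$fs
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  reliable <- TRUE
  if (length(w$values) >= 64) {
    sp <- stats::spec.pgram(w$values, taper = 0, detrend = TRUE,
                            plot = FALSE)
    f_dom <- sp$freq[which.max(sp$spec)] * w$fs
    reliable <- f_dom >= 1 / cfg$max_ibi_s && f_dom <= 1 / cfg$min_ibi_s
  }
  structure(kept, reliable = reliable)
}

#' Sub-sample refinement of a peak location
#'
#' Parabolic (3-point quadratic) interpolation of the apex around a
#' local-maximum sample, improving time resolution beyond the sampling
#' grid. Boundary samples are returned unrefined with attribute
#' `"refined" = FALSE`.
#'
#' @param w a `ppg_waveform`.
#' @param idx integer sample index of a local maximum.
#' @return Refined peak time in seconds (within half a sample of
#'   `idx`), with attribute `"refined"`.
#' @export
refine_onset <- function(w, idx) {
  n <- length(w$values)
  if (idx <= 1L || idx >= n)
    return(structure(w$t0 + (idx - 1) / w$fs, refined = FALSE))
  v <- parabola_vertex(w$values, idx, h = 1)
  structure(w$t0 + (v - 1) / w$fs, refined = TRUE)
}

#' Detect and refine beats in a band-limited PPG waveform
#'
#' Full beat segmentation: CWT candidate detection, apex selection
#' under interbeat-interval constraints, snapping to the single-scale
#' refinement trace and least-squares parabolic sub-sample refinement,
#' then location of each beat's systolic onset (the preceding valley)
#' and extraction of per-beat amplitude and rise time. Beat timing (and
#' hence the IBI series) is apex-to-apex; the valley is reported as the
#' beat boundary feature.
#'
#' @param w a band-limited `ppg_waveform` (see [bandpass()]), at least
#'   `2 * max_ibi_s` long.
#' @param cfg a [beat_config()].
#' @return Object of class `beat_series`: list with `times` (refined
#'   apex times, s), `onset_times` (preceding valleys, s), `ibis_ms`,
#'   `quality` (all `TRUE`; see [qualify_beats()]), `amplitude`,
#'   `rise_time_s`, `fs`, and attribute `"reliable"`.
#' @export
detect_beats <- function(w, cfg = beat_config()) {
  if (duration(w) < 2 * cfg$max_ibi_s)
    stop("waveform shorter than twice the maximum interbeat interval")
  cand <- detect_peaks_cwt(w, cfg)
  sel <- select_onsets(cand, w, cfg)
  n <- length(w$values)
  rtr <- xcorr_centered(w$values, ricker_wavelet(cfg$refine_width_s, w$fs))
  apex_idx <- integer(0)
  apex_t <- numeric(0)
  for (i in sel) {
    lo <- max(2L, i - cfg$snap_radius)
    hi <- min(n - 1L, i + cfg$snap_radius)
    j <- lo - 1L + which.max(rtr[lo:hi])
    v <- parabola_vertex(rtr, j, h = 2)
    apex_idx <- c(apex_idx, j)
    apex_t <- c(apex_t, w$t0 + (v - 1) / w$fs)
  }
  keep <- !duplicated(apex_idx)
  apex_idx <- apex_idx[keep]
  apex_t <- apex_t[keep]
  o <- order(apex_t)
  apex_idx <- apex_idx[o]
  apex_t <- apex_t[o]
  # preceding valley on the refinement trace
  onset_t <- numeric(length(apex_t))
  amplitude <- numeric(length(apex_t))
  rise <- numeric(length(apex_t))
  for (k in seq_along(apex_idx)) {
    lo <- if (k == 1) max(1L, apex_idx[k] - round(cfg$max_ibi_s * w$fs))
          else apex_idx[k - 1]
    seg <- rtr[lo:apex_idx[k]]
    jm <- lo - 1L + which.min(seg)
    vv <- if (jm > 1L && jm < n) parabola_vertex(-rtr, jm, h = 2) else jm
    onset_t[k] <- w$t0 + (vv - 1) / w$fs
    amplitude[k] <- w$values[apex_idx[k]] - w$values[jm]
    rise[k] <- apex_t[k] - onset_t[k]
  }
  structure(list(times = apex_t, onset_times = onset_t,
                 ibis_ms = diff(apex_t) * 1000,
                 quality = rep(TRUE, length(apex_t)),
                 amplitude = amplitude, rise_time_s = rise, fs = w$fs),
            class = "beat_series", reliable = attr(sel, "reliable"))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats, %d qualified, mean IBI %.0f ms>\n",
              length(x$times), sum(x$quality),
              if (length(x$ibis_ms)) mean(x$ibis_ms) else NA))
  invisible(x)
}

# Sample-index support [start, end) of each beat: apex-centered
# segments bounded by the surrounding onsets (last beat extends one
# median IBI or to the end of the record).
beat_supports <- function(series, w) {
  n_beats <- length(series$times)
  n <- length(w$values)
  med_ibi <- stats::median(diff(series$times))
  starts <- pmax(1L, round((series$onset_times - w$t0) * w$fs) + 1L)
  ends <- integer(n_beats)
  if (n_beats > 1) ends[seq_len(n_beats - 1)] <- starts[-1]
  ends[n_beats] <- min(n, round((series$times[n_beats] + med_ibi - w$t0) *
                                  w$fs) + 1L)
  cbind(start = starts, end = pmax(starts + 2L, ends))
}

#' Per-beat qualification
#'
#' A beat qualifies when (a) the Pearson correlation of its segment,
#' resampled to a fixed 50-point grid, with the pointwise-median beat
#' template is at least `template_corr_min`; (b) at least half of its
#' local short-time spectral power lies in `stft_band_hz` (a 4-s
#' Hann-windowed periodogram centered on the beat); and (c) no motion
#' envelope excursion overlaps its support. Fewer than 3 beats leave
#' every beat unqualified (no template can be formed).
#'
#' @param series a `beat_series` from [detect_beats()].
#' @param w the band-limited `ppg_waveform` the series was detected on.
#' @param m optional `ppg_motion` trace.
#' @param cfg a [beat_config()].
#' @return The `beat_series` with its `quality` flags updated.
#' @export
qualify_beats <- function(series, w, m = NULL, cfg = beat_config()) {
  n_beats <- length(series$times)
  if (n_beats < 3) {
    series$quality <- rep(FALSE, n_beats)
    return(series)
  }
  sup <- beat_supports(series, w)
  grid <- seq(0, 1, length.out = 50)
  segs <- vapply(seq_len(n_beats), function(k) {
    i <- sup[k, "start"]:(sup[k, "end"] - 1L)
    y <- w$values[i]
    stats::approx(seq(0, 1, length.out = length(y)), y, grid)$y
  }, numeric(50))
  template <- apply(segs, 1, stats::median)
  corr_ok <- vapply(seq_len(n_beats), function(k) {
    if (stats::sd(segs[, k]) == 0 || stats::sd(template) == 0) return(FALSE)
    stats::cor(segs[, k], template) >= cfg$template_corr_min
  }, logical(1))
  stft_ok <- vapply(seq_len(n_beats), function(k) {
    stft_band_fraction(w, sup[k, "start"], sup[k, "end"],
                       cfg$stft_band_hz) >= 0.5
  }, logical(1))
  motion_ok <- rep(TRUE, n_beats)
  if (!is.null(m)) {
    dev <- abs(m$magnitude - stats::median(m$magnitude))
    tm <- sample_times(m)
    motion_ok <- vapply(seq_len(n_beats), function(k) {
      t0k <- w$t0 + (sup[k, "start"] - 1L) / w$fs
      t1k <- w$t0 + (sup[k, "end"] - 1L) / w$fs
      inside <- tm >= t0k & tm < t1k
      !any(dev[inside] > cfg$motion_threshold)
    }, logical(1))
  }
  series$quality <- corr_ok & stft_ok & motion_ok
  series
}

# Fraction of short-time spectral power in [band[1], band[2]] Hz for
# the Hann-windowed samples [i0, i1). Confined to the beat's own
# support so that one corrupted beat cannot contaminate the spectral
# check of its neighbors.
stft_band_fraction <- function(w, i0, i1, band) {
  n <- length(w$values)
  i0 <- max(1L, i0)
  i1 <- min(n, i1 - 1L)
  y <- w$values[i0:i1]
  ny <- length(y)
  if (ny < 8L) return(0)
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, ny - 1) / (ny - 1))
  m <- stats::nextn(4L * ny, 2)  # zero-pad for band integration
  Y <- Mod(stats::fft(c((y - mean(y)) * han, rep(0, m - ny))))^2
  freqs <- (seq_len(m) - 1) * w$fs / m
  half_i <- freqs <= w$fs / 2 & freqs > 0
  tot <- sum(Y[half_i])
  if (tot == 0) return(0)
  sum(Y[half_i & freqs >= band[1] & freqs <= band[2]]) / tot
}

#' Interbeat intervals between qualified adjacent beats
#'
#' An IBI is retained only when both bounding beats are qualified and
#' the interval lies in the admissible `[min_ibi_s, max_ibi_s]` range
#' (intervals spanning a detection gap are never emitted).
#'
#' @param series a `beat_series`.
#' @param cfg a [beat_config()].
#' @return Numeric vector of IBIs in ms.
#' @export
beats_to_ibis <- function(series, cfg = beat_config()) {
  qualified_ibi_table(series, cfg)$ibi_ms
}

# IBIs with their starting beat time, restricted to qualified pairs and
# the admissible range; used for window assignment.
qualified_ibi_table <- function(series, cfg = beat_config()) {
  nb <- length(series$times)
  if (nb < 2)
    return(data.frame(t_start = numeric(0), ibi_ms = numeric(0)))
  ok <- series$quality[-nb] & series$quality[-1]
  ibi <- series$ibis_ms
  inrange <- ibi >= cfg$min_ibi_s * 1000 & ibi <= cfg$max_ibi_s * 1000
  keep <- ok & inrange
  data.frame(t_start = series$times[-nb][keep], ibi_ms = ibi[keep])
}
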