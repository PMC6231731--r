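# Per-window biometrics: robust ectopic-interval removal, heart rate,
# time-domain heart-rate variability (SDNN, RMSSD) and respiration
# rate estimated from baseline wander and from the frequency
# modulation of the heart period, fused with threshold-based
# qualification.

#' Outlier-removal configuration for interbeat intervals
#'
#' An interbeat interval is an outlier when its logarithm lies more
#' than `mad_threshold` median absolute deviations from the median
#' log-IBI of the full recording. The MAD is unscaled (no 1.4826
#' normal-consistency factor). Outliers are removed without
#' replacement.
#'
#' @param mad_threshold dimensionless threshold (default 6.25).
#' @return List of class `outlier_config`.
#' @export
outlier_config <- function(mad_threshold = 6.25) {
  stopifnot(mad_threshold > 0)
  structure(list(mad_threshold = mad_threshold), class = "outlier_config")
}

#' Remove ectopic / non-normal interbeat intervals
#'
#' Median and MAD of the log-IBIs are computed over `ref_ibis_ms`
#' (conventionally the full recording's IBI series) and the threshold
#' is applied to `ibis_ms` (e.g. one window's IBIs). When the MAD is
#' zero (e.g. all reference IBIs equal) the rule falls back to an
#' absolute log-deviation threshold of `log(1.5)` and the result is
#' flagged.
#'
#' @param ibis_ms IBIs to filter, ms.
#' @param cfg an [outlier_config()].
#' @param ref_ibis_ms IBIs defining the median/MAD statistics; defaults
#'   to `ibis_ms` itself.
#' @return List with `kept` (surviving IBIs), `removed` (integer
#'   indices into `ibis_ms`), and `mad_zero_fallback` (logical).
#' @export
remove_outliers <- function(ibis_ms, cfg = outlier_config(),
                            ref_ibis_ms = ibis_ms) {
  if (!length(ibis_ms))
    return(list(kept = numeric(0), removed = integer(0),
                mad_zero_fallback = FALSE))
  stopifnot(all(ibis_ms > 0), all(ref_ibis_ms > 0))
  lg <- log(ref_ibis_ms)
  med <- stats::median(lg)
  mad0 <- stats::median(abs(lg - med))
  dev <- abs(log(ibis_ms) - med)
  if (mad0 == 0) {
    removed <- which(dev > log(1.5))
    fallback <- TRUE
  } else {
    removed <- which(dev > cfg$mad_threshold * mad0)
    fallback <- FALSE
  }
  kept <- if (length(removed)) ibis_ms[-removed] else ibis_ms
  list(kept = kept, removed = removed, mad_zero_fallback = fallback)
}

#' Heart rate from interbeat intervals
#'
#' `60000 / mean(ibis_ms)` in beats per minute. Minimum-beat gating is
#' applied by [compute_window_metrics()], not here.
#'
#' @param ibis_ms IBIs in ms.
#' @return Heart rate in bpm (`NA` for an empty input).
#' @export
hr_bpm <- function(ibis_ms) {
  if (!length(ibis_ms)) return(NA_real_)
  60000 / mean(ibis_ms)
}

#' SDNN: standard deviation of normal-to-normal intervals
#'
#' Sample standard deviation (n - 1 denominator) of the
#' outlier-filtered IBIs in a window.
#'
#' @param ibis_ms IBIs in ms.
#' @param population use the population (divide by n) form instead.
#' @return SDNN in ms (`NA` with fewer than 2 IBIs).
#' @export
sdnn_ms <- function(ibis_ms, population = FALSE) {
  n <- length(ibis_ms)
  if (n < 2) return(NA_real_)
  s <- stats::sd(ibis_ms)
  if (population) s * sqrt((n - 1) / n) else s
}

#' RMSSD: root mean square of successive differences
#'
#' @param ibis_ms IBIs in ms (adjacent qualified pairs).
#' @return RMSSD in ms (`NA` with fewer than 2 IBIs).
#' @export
rmssd_ms <- function(ibis_ms) {
  if (length(ibis_ms) < 2) return(NA_real_)
  sqrt(mean(diff(ibis_ms)^2))
}

#' Vitals configuration
#'
#' @param min_beats_per_min minimum beats per 60 s of window for HR and
#'   HRV to be emitted; scales linearly with window duration.
#' @param rr_band_hz respiratory analysis band in Hz (default 0.1--0.5,
#'   i.e. 6--30 breaths per minute, covering resting adults).
#' @param rr_quality_min quality threshold below which a single-method
#'   respiration estimate is discarded.
#' @param rr_agree_brpm maximum disagreement (breaths per minute)
#'   between the baseline-wander and frequency-modulation estimates for
#'   fusion; beyond it the fused estimate is withheld.
#' @param resample_hz uniform resampling rate for the instantaneous
#'   heart-rate series used by the frequency-modulation method.
#' @param outlier an [outlier_config()].
#' @return List of class `vitals_config`.
#' @export
vitals_config <- function(min_beats_per_min = 30, rr_band_hz = c(0.1, 0.5),
                          rr_quality_min = 0.5, rr_agree_brpm = 4,
                          resample_hz = 4, outlier = outlier_config()) {
  structure(list(min_beats_per_min = min_beats_per_min,
                 rr_band_hz = rr_band_hz, rr_quality_min = rr_quality_min,
                 rr_agree_brpm = rr_agree_brpm, resample_hz = resample_hz,
                 outlier = outlier),
            class = "vitals_config")
}

#' Respiration rate from baseline wander
#'
#' Time-domain method: band-limit the raw (pre-highpass) window to the
#' respiratory band, detect inspiration/expiration cycles with the
#' Ricker wavelet peak detector, and convert the mean breath-to-breath
#' interval to breaths per minute. Quality is the regularity of the
#' cycle lengths, `1 - CV`.
#'
#' @param w_raw the raw `ppg_waveform` window (baseline wander intact).
#' @param cfg a [vitals_config()].
#' @return List with `rr_brpm` and `quality`, or `NULL` when fewer than
#'   2 full cycles are found or the rate falls outside the band.
#' @export
rr_baseline_wander <- function(w_raw, cfg = vitals_config()) {
  band <- cfg$rr_band_hz
  y <- bandpass_vec(w_raw$values, w_raw$fs, band[1], band[2])
  if (stats::sd(y) == 0) return(NULL)
  widths <- exp(seq(log(0.25 / band[2]), log(0.25 / band[1]), length.out = 6))
  cw <- rowMeans(cwt_ricker(y, widths, w_raw$fs))
  pk <- local_maxima(cw)
  pk <- pk[cw[pk] > 0.3 * max(cw)]
  if (length(pk) < 3) return(NULL)
  cycles <- diff((pk - 1) / w_raw$fs)
  rr <- 60 / mean(cycles)
  if (rr < band[1] * 60 || rr > band[2] * 60) return(NULL)
  quality <- max(0, 1 - stats::sd(cycles) / mean(cycles))
  list(rr_brpm = rr, quality = quality)
}

#' Respiration rate from heart-period frequency modulation
#'
#' Frequency-domain method: the instantaneous heart-rate series
#' (one value per qualified IBI) is resampled to a uniform grid by
#' linear interpolation, a complex Morlet continuous wavelet transform
#' is evaluated over the respiratory band, and the respiration ridge is
#' traced as the per-time power argmax; the reported rate is the median
#' ridge frequency times 60. Quality is the fraction of time-averaged
#' transform power concentrated within 0.05 Hz of the ridge.
#'
#' @param ibi_times beat times (s) starting each IBI.
#' @param ibis_ms the corresponding IBIs in ms (outlier-filtered).
#' @param cfg a [vitals_config()].
#' @return List with `rr_brpm` and `quality`, or `NULL` when too few
#'   beats or too short a span is available.
#' @export
rr_frequency_modulation <- function(ibi_times, ibis_ms,
                                    cfg = vitals_config()) {
  if (length(ibis_ms) < 8 || diff(range(ibi_times)) < 10) return(NULL)
  band <- cfg$rr_band_hz
  hr_series <- 60000 / ibis_ms
  g <- seq(min(ibi_times), max(ibi_times), by = 1 / cfg$resample_hz)
  y <- stats::approx(ibi_times, hr_series, g)$y
  y <- y - mean(y)
  if (stats::sd(y) == 0) return(NULL)
  freqs <- seq(band[1], band[2], by = 0.01)
  P <- cwt_morlet_power(y, freqs, cfg$resample_hz)
  ridge <- freqs[apply(P, 1, which.max)]
  f_med <- stats::median(ridge)
  sp <- colMeans(P)
  quality <- sum(sp[abs(freqs - f_med) <= 0.05]) / sum(sp)
  list(rr_brpm = f_med * 60, quality = quality)
}

#' Fuse the two respiration-rate estimates
#'
#' Threshold-based qualification and fusion: estimates with quality
#' below `rr_quality_min` are discarded; if both survive and agree
#' within `rr_agree_brpm` the quality-weighted mean is returned; if
#' they disagree the estimate is withheld; a single survivor is
#' returned as is.
#'
#' @param bw,fm results of [rr_baseline_wander()] /
#'   [rr_frequency_modulation()] (each `NULL` or
#'   `list(rr_brpm, quality)`).
#' @param cfg a [vitals_config()].
#' @return Respiration rate in breaths per minute, or `NA` when no
#'   qualified estimate remains.
#' @export
rr_fuse <- function(bw, fm, cfg = vitals_config()) {
  ok <- function(e) !is.null(e) && e$quality >= cfg$rr_quality_min
  b <- ok(bw); f <- ok(fm)
  if (b && f) {
    if (abs(bw$rr_brpm - fm$rr_brpm) > cfg$rr_agree_brpm) return(NA_real_)
    return((bw$rr_brpm * bw$quality + fm$rr_brpm * fm$quality) /
             (bw$quality + fm$quality))
  }
  if (b) return(bw$rr_brpm)
  if (f) return(fm$rr_brpm)
  NA_real_
}

#' Compute per-window vital signs for a recording
#'
#' Orchestrates the full chain on one recording: bandpass filtering,
#' beat detection and qualification over the whole recording,
#' recording-level outlier statistics, then per window: HNR
#' qualification and motion gating, minimum-beat gating, and the
#' HR / SDNN / RMSSD / respiration-rate estimators with per-metric
#' validity flags. Metrics that cannot be computed are absent (`NA`),
#' never errors.
#'
#' @param ppg_raw the raw `ppg_waveform` recording.
#' @param motion optional `ppg_motion` trace.
#' @param window_s window duration in seconds (60, 45 or 30
#'   conventionally).
#' @param qcfg,bcfg,vcfg configuration objects; see [quality_config()],
#'   [beat_config()], [vitals_config()].
#' @param lo,hi cardiovascular bandpass edges in Hz.
#' @return Data frame of class `window_metrics`, one row per complete
#'   window: `window_index`, `window_start_s`, `hr_bpm`, `sdnn_ms`,
#'   `rmssd_ms`, `rr_brpm`, `hnr_db`, `n_beats`, `n_outliers_removed`,
#'   `qualified`, `motion_flagged`, `valid_hr`, `valid_sdnn`,
#'   `valid_rmssd`, `valid_rr`.
#' @export
compute_window_metrics <- function(ppg_raw, motion = NULL, window_s = 60,
                                   qcfg = quality_config(),
                                   bcfg = beat_config(),
                                   vcfg = vitals_config(),
                                   lo = 0.3, hi = 10) {
  empty <- data.frame(window_index = integer(0), window_start_s = numeric(0),
                      hr_bpm = numeric(0), sdnn_ms = numeric(0),
                      rmssd_ms = numeric(0), rr_brpm = numeric(0),
                      hnr_db = numeric(0), n_beats = integer(0),
                      n_outliers_removed = integer(0),
                      qualified = logical(0), motion_flagged = logical(0),
                      valid_hr = logical(0), valid_sdnn = logical(0),
                      valid_rmssd = logical(0), valid_rr = logical(0))
  class(empty) <- c("window_metrics", "data.frame")
  if (is.null(ppg_raw) || duration(ppg_raw) < window_s) return(empty)
  xb <- bandpass(ppg_raw, lo, hi)
  wins <- segment_windows(ppg_raw, window_s)
  series <- detect_beats(xb, bcfg)
  series <- qualify_beats(series, xb, motion, bcfg)
  rec_tab <- qualified_ibi_table(series, bcfg)
  min_beats <- ceiling(vcfg$min_beats_per_min * window_s / 60)
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    win <- wins[i, ]
    wb <- slice_window(xb, win)
    hnr <- hnr_recording(wb, qcfg)
    mflag <- motion_flag(motion, win, qcfg$motion_threshold)
    qok <- qualify(hnr, mflag, qcfg)
    out <- data.frame(window_index = win$index, window_start_s = win$start,
                      hr_bpm = NA_real_, sdnn_ms = NA_real_,
                      rmssd_ms = NA_real_, rr_brpm = NA_real_,
                      hnr_db = hnr$mean_db, n_beats = 0L,
                      n_outliers_removed = 0L, qualified = qok,
                      motion_flagged = mflag, valid_hr = FALSE,
                      valid_sdnn = FALSE, valid_rmssd = FALSE,
                      valid_rr = FALSE)
    if (!qok) return(out)
    inw <- rec_tab$t_start >= win$start &
      rec_tab$t_start < win$start + win$duration
    filt <- remove_outliers(rec_tab$ibi_ms[inw], vcfg$outlier,
                            ref_ibis_ms = rec_tab$ibi_ms)
    kept_t <- rec_tab$t_start[inw]
    if (length(filt$removed)) kept_t <- kept_t[-filt$removed]
    ib <- filt$kept
    out$n_outliers_removed <- length(filt$removed)
    out$n_beats <- sum(series$quality &
                         series$times >= win$start &
                         series$times < win$start + win$duration)
    enough <- out$n_beats >= min_beats &&
      out$n_beats >= cfg_expected_beats(series, win, bcfg)
    if (enough && length(ib) >= 2) {
      out$hr_bpm <- hr_bpm(ib)
      out$sdnn_ms <- sdnn_ms(ib)
      out$rmssd_ms <- rmssd_ms(ib)
      out$valid_hr <- is.finite(out$hr_bpm)
      out$valid_sdnn <- is.finite(out$sdnn_ms)
      out$valid_rmssd <- is.finite(out$rmssd_ms)
    }
    bw <- rr_baseline_wander(slice_window(ppg_raw, win), vcfg)
    fm <- if (length(ib) >= 8)
      rr_frequency_modulation(kept_t, ib, vcfg) else NULL
    rr <- rr_fuse(bw, fm, vcfg)
    out$rr_brpm <- rr
    out$valid_rr <- is.finite(rr)
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("window_metrics", "data.frame")
  res
}

# Minimum qualified beats for a window: min_qualified_frac of the
# expected beat count given the recording's median IBI.
cfg_expected_beats <- function(series, win, bcfg) {
  ibis <- series$ibis_ms
  if (!length(ibis)) return(Inf)
  expected <- win$duration / (stats::median(ibis) / 1000)
  bcfg$min_qualified_frac * expected
}
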