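# Signal qualification by harmonic-to-noise ratio (HNR). The HNR of a
# short window is read off the peak of the normalized autocorrelation
# of the mean-removed, band-limited signal (Boersma's method): a
# perfectly periodic signal has r* -> 1, pure noise r* -> 0, and
# HNR = 10 log10(r* / (1 - r*)) dB. Recordings whose mean HNR falls
# below a threshold, or whose motion envelope is elevated, do not
# qualify for vital-sign analysis.

#' Quality-gating configuration
#'
#' @param hnr_window_s HNR analysis window length in seconds (default
#'   6, per-window HNR).
#' @param hnr_step_s spacing of the overlapping window centers in
#'   seconds (default 1).
#' @param hnr_threshold_db qualification threshold on the mean HNR of a
#'   recording, in dB. The threshold's existence is part of the method;
#'   its value is an assumption here (3 dB) and should be calibrated
#'   per device.
#' @param motion_threshold threshold on the robust motion envelope
#'   (95th percentile of |magnitude - median|), in motion units.
#' @param lag_search_s two-element range of autocorrelation lags
#'   searched, seconds. The default (0.33, 2.0) spans heart periods of
#'   30--180 bpm, restricting the measure to the cardiovascular
#'   component.
#' @return List of class `quality_config`.
#' @export
quality_config <- function(hnr_window_s = 6, hnr_step_s = 1,
                           hnr_threshold_db = 3, motion_threshold = 0.5,
                           lag_search_s = c(1 / 3, 2)) {
  stopifnot(hnr_window_s > hnr_step_s, hnr_step_s > 0,
            length(lag_search_s) == 2, lag_search_s[1] < lag_search_s[2])
  structure(list(hnr_window_s = hnr_window_s, hnr_step_s = hnr_step_s,
                 hnr_threshold_db = hnr_threshold_db,
                 motion_threshold = motion_threshold,
                 lag_search_s = lag_search_s),
            class = "quality_config")
}

#' Harmonic-to-noise ratio of one short window
#'
#' Boersma's estimator: the mean-removed signal is tapered with a Hann
#' window, its normalized autocorrelation is divided by the window's
#' own normalized autocorrelation (undoing the taper bias), the peak
#' `r*` over the configured lag range is sharpened by parabolic
#' interpolation, and the result is `10 log10(r* / (1 - r*))` clipped
#' to [-20, +40] dB. The input should already be band-limited to the
#' cardiovascular band (see [bandpass()]); respiratory components
#' below 0.3 Hz would otherwise count as "harmonic" signal.
#'
#' @param w a `ppg_waveform`, at least twice the maximum search lag
#'   long.
#' @param lag_search_s lag range searched, seconds.
#' @return HNR in dB (scalar).
#' @export
hnr_window <- function(w, lag_search_s = c(1 / 3, 2)) {
  x <- w$values - mean(w$values)
  n <- length(x)
  if (n < 2 * lag_search_s[2] * w$fs)
    stop("window shorter than twice the maximum search lag")
  if (stats::sd(x) == 0) stop("flat signal")
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  m <- stats::nextn(2L * n, 2)
  acf_norm <- function(v) {
    X <- stats::fft(c(v, rep(0, m - n)))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(n)]
    r / r[1]
  }
  r <- acf_norm(x * han) / acf_norm(han)
  taus <- seq(round(lag_search_s[1] * w$fs), round(lag_search_s[2] * w$fs))
  taus <- taus[taus >= 1 & taus < n - 1]
  rt <- r[taus + 1]
  i <- which.max(rt)
  r_star <- rt[i]
  if (i > 1 && i < length(rt)) {
    y1 <- rt[i - 1]; y2 <- rt[i]; y3 <- rt[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) r_star <- y2 - (y1 - y3)^2 / (8 * den)
  }
  hnr_db_from_r(r_star)
}

# r* -> dB with the documented caps (the r* -> 1 singularity is kept
# finite at +40 dB; nonpositive r* maps to the -20 dB floor).
hnr_db_from_r <- function(r_star) {
  if (r_star <= 0) return(-20)
  if (r_star >= 1) return(40)
  min(40, max(-20, 10 * log10(r_star / (1 - r_star))))
}

#' HNR of a recording from overlapping windows
#'
#' The HNR is computed for `hnr_window_s`-second windows whose centers
#' are `hnr_step_s` apart, starting at `hnr_window_s / 2` so that every
#' window fits entirely (no zero padding); the recording's HNR is the
#' arithmetic mean of the per-window values. A 60-s recording at the
#' 6-s/1-s defaults yields 55 windows with centers at 3..57 s.
#'
#' @param w a band-limited `ppg_waveform`.
#' @param cfg a [quality_config()].
#' @return List of class `hnr_result` with `per_window_db`, `mean_db`,
#'   `n_windows`, and `centers_s`.
#' @export
hnr_recording <- function(w, cfg = quality_config()) {
  dur <- duration(w)
  hw <- cfg$hnr_window_s
  if (dur < hw) stop("recording shorter than one HNR window")
  centers <- seq(hw / 2, dur - hw / 2 + 1e-9, by = cfg$hnr_step_s)
  vals <- vapply(centers, function(cc) {
    win <- list(start = w$t0 + cc - hw / 2, duration = hw)
    hnr_window(slice_window(w, win), cfg$lag_search_s)
  }, numeric(1))
  structure(list(per_window_db = vals, mean_db = mean(vals),
                 n_windows = length(vals), centers_s = centers),
            class = "hnr_result")
}

#' @export
print.hnr_result <- function(x, ...) {
  cat(sprintf("<hnr_result: %d windows, mean %.2f dB (range %.2f..%.2f)>\n",
              x$n_windows, x$mean_db, min(x$per_window_db),
              max(x$per_window_db)))
  invisible(x)
}

#' Motion flag for one analysis window
#'
#' A window is flagged when the robust motion envelope — the 95th
#' percentile of |magnitude - median(magnitude)| over the window —
#' exceeds the threshold. With no motion samples in the window the flag
#' is `FALSE` with a warning (motion data are optional).
#'
#' @param m a `ppg_motion` trace or `NULL`.
#' @param win a window (`start`, `duration` in seconds).
#' @param threshold envelope threshold, motion units.
#' @return Logical flag.
#' @export
motion_flag <- function(m, win, threshold = 0.5) {
  if (is.null(m)) return(FALSE)
  mag <- slice_motion(m, win)
  if (length(mag) == 0) {
    warning("no motion samples in window; motion gating skipped")
    return(FALSE)
  }
  env <- stats::quantile(abs(mag - stats::median(mag)), 0.95, names = FALSE)
  is.finite(threshold) && env > threshold
}

#' Qualification decision for a recording window
#'
#' A 60-second measurement qualifies for vital-sign analysis when its
#' mean HNR meets the threshold and it is not motion flagged.
#'
#' @param hnr an [hnr_recording()] result.
#' @param motion_flagged logical from [motion_flag()].
#' @param cfg a [quality_config()].
#' @return Logical.
#' @export
qualify <- function(hnr, motion_flagged, cfg = quality_config()) {
  hnr$mean_db >= cfg$hnr_threshold_db && !motion_flagged
}
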