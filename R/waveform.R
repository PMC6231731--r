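#' Uniformly sampled waveform
#'
#' Container for one channel of a uniformly sampled signal, the basic
#' currency of the package. PPG channels are conventionally sampled at
#' 86 Hz by the wristband class of devices this toolkit targets, but any
#' positive sampling rate is accepted.
#'
#' @param values numeric vector of samples (arbitrary units); must be
#'   finite and non-empty.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time of the first sample in seconds.
#' @param label channel name, e.g. `"ir"` or `"red"`.
#' @return An object of class `ppg_waveform`: a list with elements
#'   `values`, `fs`, `t0`, `label`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 1.2 * (0:859) / 86), fs = 86)
#' duration(w)
waveform <- function(values, fs, t0 = 0, label = "ir") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty signal")
  if (!all(is.finite(values))) stop("waveform contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  structure(list(values = values, fs = fs, t0 = t0, label = label),
            class = "ppg_waveform")
}

#' @export
print.ppg_waveform <- function(x, ...) {
  cat(sprintf("<ppg_waveform '%s': %d samples @ %.6g Hz, %.2f s, t0 = %.3f s>\n",
              x$label, length(x$values), x$fs, duration(x), x$t0))
  invisible(x)
}

#' Duration of a waveform or motion trace in seconds
#' @param w a `ppg_waveform` or `ppg_motion` object.
#' @return Duration `length(values) / fs` in seconds.
#' @export
duration <- function(w) length(w$values %||% w$magnitude) / w$fs

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample times of a waveform
#' @param w a `ppg_waveform` or `ppg_motion`.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(w) {
  n <- length(w$values %||% w$magnitude)
  w$t0 + (seq_len(n) - 1) / w$fs
}

#' Three-axis motion magnitude trace
#'
#' Motion magnitude series (e.g. the Euclidean norm of 3-axis
#' accelerometer samples) used to gate PPG segments corrupted by wrist
#' movement. Device motion data are nominally sampled at 10 Hz.
#'
#' @param magnitude numeric vector of non-negative motion magnitudes.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return An object of class `ppg_motion`.
#' @export
motion_trace <- function(magnitude, fs = 10, t0 = 0) {
  magnitude <- as.numeric(magnitude)
  if (length(magnitude) < 1L) stop("empty motion trace")
  if (!all(is.finite(magnitude))) stop("motion trace contains non-finite values")
  if (any(magnitude < 0)) stop("motion magnitude must be non-negative")
  if (fs <= 0) stop("fs must be positive")
  structure(list(magnitude = magnitude, fs = fs, t0 = t0),
            class = "ppg_motion")
}

#' @export
print.ppg_motion <- function(x, ...) {
  cat(sprintf("<ppg_motion: %d samples @ %.6g Hz, %.2f s>\n",
              length(x$magnitude), x$fs, duration(x)))
  invisible(x)
}

#' Segment a waveform into nonoverlapping analysis windows
#'
#' Tiles the waveform with contiguous, nonoverlapping windows of the
#' given duration starting at `t0`. A trailing remainder shorter than
#' one window is discarded, matching the convention of reporting vitals
#' over complete 60-second (or 45/30-second) measurements only.
#'
#' @param w a `ppg_waveform`.
#' @param duration_s window duration in seconds (> 0); 60 by default.
#' @return A data frame of class `ppg_windows` with columns `index`
#'   (0-based), `start` (seconds) and `duration`. Zero rows when the
#'   waveform is shorter than one window.
#' @export
#' @examples
#' w <- waveform(rnorm(86 * 366), fs = 86)
#' nrow(segment_windows(w, 60))  # 6; the trailing 6 s are discarded
segment_windows <- function(w, duration_s = 60) {
  if (is.null(w) || length(w$values) == 0L) stop("empty signal")
  if (duration_s <= 0) stop("window duration must be positive")
  k <- floor(duration(w) / duration_s + 1e-9)
  out <- data.frame(index = seq_len(k) - 1L,
                    start = w$t0 + (seq_len(k) - 1) * duration_s,
                    duration = rep(duration_s, k))
  class(out) <- c("ppg_windows", "data.frame")
  out
}

#' Extract one window from a waveform
#'
#' Sample-aligned, half-open extraction: samples with indices in
#' `[round((start - t0) * fs), round((start - t0 + duration) * fs))`.
#'
#' @param w a `ppg_waveform`.
#' @param win one row of a [segment_windows()] result, or any list with
#'   `start` and `duration` in seconds.
#' @return A `ppg_waveform` holding the window's samples, with `t0` set
#'   to the window start.
#' @export
slice_window <- function(w, win) {
  start <- win$start
  dur <- win$duration
  i0 <- round((start - w$t0) * w$fs)
  i1 <- i0 + round(dur * w$fs)  # exclusive
  if (i0 < 0 || i1 > length(w$values))
    stop("window out of waveform range")
  waveform(w$values[(i0 + 1):i1], fs = w$fs, t0 = start, label = w$label)
}

#' Slice a motion trace over a window (internal)
#' @noRd
slice_motion <- function(m, win) {
  i0 <- round((win$start - m$t0) * m$fs)
  i1 <- i0 + round(win$duration * m$fs)
  i0 <- max(i0, 0L)
  i1 <- min(i1, length(m$magnitude))
  if (i1 <= i0) return(numeric(0))
  m$magnitude[(i0 + 1):i1]
}

# Forward-backward filtering with reflection padding. signal::filtfilt
# applies no edge treatment, which leaves large startup transients at
# 0.3 Hz corner frequencies; reflecting ~10 s of signal about each end
# point suppresses them.
reflect_filtfilt <- function(flt, x, fs, pad_s = 10) {
  n <- length(x)
  pad <- min(n - 1L, max(1L, round(pad_s * fs)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(flt, xp)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Band-limits a waveform with zero-phase Butterworth stages: two
#' cascaded 4th-order high-pass passes at the low edge (16th-order
#' magnitude response) and one 4th-order low-pass at the high edge,
#' each run forward and backward. The cascade of low-order stages
#' stays numerically well conditioned at very low normalized corner
#' frequencies (0.3 Hz at 86 Hz sampling), and the steep low edge is
#' what actually removes respiratory components sitting just below
#' the band — a shallow edge would leak them into the
#' harmonic-to-noise ratio. Zero-phase filtering preserves beat timing,
#' which matters because interbeat intervals are read off filtered
#' signals. The default band 0.3--10 Hz isolates the cardiovascular
#' component of a PPG signal: it removes baseline wander and other
#' respiratory contributions below 0.3 Hz and wideband noise above
#' 10 Hz.
#'
#' @param w a `ppg_waveform`.
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2` required.
#' @return A filtered `ppg_waveform` of identical length and sampling
#'   rate, with (near-)zero mean.
#' @export
bandpass <- function(w, lo = 0.3, hi = 10) {
  if (hi >= w$fs / 2) stop("band above Nyquist")
  if (lo <= 0 || lo >= hi) stop("require 0 < lo < hi")
  hp <- signal::butter(4, lo / (w$fs / 2), type = "high")
  lp <- signal::butter(4, hi / (w$fs / 2), type = "low")
  x <- w$values - mean(w$values)  # conditioning: DC out before the IIR
  y <- reflect_filtfilt(hp, reflect_filtfilt(hp, x, w$fs), w$fs)
  y <- reflect_filtfilt(lp, y, w$fs)
  waveform(y, fs = w$fs, t0 = w$t0, label = w$label)
}

# Zero-phase lowpass/highpass used by the respiration band-limit.
#' @noRd
bandpass_vec <- function(x, fs, lo, hi, order = 2) {
  flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  reflect_filtfilt(flt, x, fs, pad_s = max(10, 2 / lo))
}
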