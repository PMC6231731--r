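# Continuous wavelet transform primitives shared by beat detection and
# respiration analysis. These are deliberately small: a Ricker
# (Mexican-hat) transform for peak detection and a complex Morlet
# transform for ridge tracing in the respiratory band.

#' Ricker (Mexican-hat) wavelet sampled at a given rate
#'
#' @param width characteristic width `a` in seconds; the wavelet is
#'   `(1 - (t/a)^2) exp(-t^2 / (2 a^2))`, truncated at `|t| = 5 a` and
#'   normalized to unit energy.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of odd length.
#' @export
ricker_wavelet <- function(width, fs) {
  L <- ceiling(5 * width * fs)
  s <- ((-L):L) / fs / width
  k <- (1 - s^2) * exp(-s^2 / 2)
  k / sqrt(sum(k^2))
}

# Centered cross-correlation of x with kernel k (odd length), constant
# edge padding; returns a vector aligned with x.
xcorr_centered <- function(x, k) {
  L <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1], L), x, rep(x[n], L))
  as.numeric(stats::convolve(xp, rev(k), type = "filter"))
}

#' Ricker continuous wavelet transform
#'
#' @param x numeric signal.
#' @param widths wavelet widths in seconds (one column per width).
#' @param fs sampling rate in Hz.
#' @return A `length(x)` by `length(widths)` matrix of coefficients.
#' @export
cwt_ricker <- function(x, widths, fs) {
  vapply(widths, function(a) xcorr_centered(x, ricker_wavelet(a, fs)),
         numeric(length(x)))
}

# Complex Morlet transform restricted to a set of analysis frequencies.
# Center frequency f maps to scale w0 / (2 pi f); w0 = 5 keeps the
# wavelet support short enough that respiratory frequencies down to
# 0.1 Hz remain measurable inside a 60-s window.
cwt_morlet_power <- function(x, freqs, fs, w0 = 5) {
  n <- length(x)
  vapply(freqs, function(f) {
    a <- w0 / (2 * pi * f)
    L <- ceiling(4 * a * fs)
    tt <- ((-L):L) / fs
    k <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * a^2))
    k <- k / sqrt(sum(Mod(k)^2))
    xp <- c(rep(0, L), x, rep(0, L))
    Mod(stats::convolve(xp, Conj(rev(k)), type = "filter"))^2
  }, numeric(n))
}

# Indices of strict-left / weak-right local maxima of y (interior only).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Least-squares parabola vertex through samples (i-h)..(i+h) of y;
# returns a fractional index. Falls back to i when the fit is not
# concave or the support leaves the vector.
parabola_vertex <- function(y, i, h = 2) {
  if (i - h < 1L || i + h > length(y)) return(i)
  z <- (-h):h
  co <- stats::.lm.fit(cbind(1, z, z^2), y[(i - h):(i + h)])$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) return(i)
  d <- -co[2] / (2 * co[3])
  i + max(-h, min(h, d))
}
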