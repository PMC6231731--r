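# Synthetic PPG generator with retained ground truth. This is the
# package's stand-in for human recordings: it renders a pulsatile
# waveform with a dicrotic (diastolic) component, respiratory baseline
# wander, amplitude modulation and frequency modulation (respiratory
# sinus arrhythmia), optional white noise and motion-artifact
# transients, while keeping the true beat times, interbeat intervals
# and respiration rate for parameter-recovery tests.

#' Pulse shape parameters
#'
#' Each beat is rendered as a systolic Gaussian bump plus a delayed,
#' smaller dicrotic Gaussian bump. Wrist PPG morphology has the
#' diastolic peak close to the systolic peak, hence the short default
#' delay.
#'
#' @param systolic_amp systolic amplitude, arbitrary units.
#' @param systolic_width systolic Gaussian sigma in seconds.
#' @param dicrotic_amp_frac dicrotic amplitude as a fraction of the
#'   systolic amplitude (0--1).
#' @param dicrotic_delay systolic-to-dicrotic delay in seconds; must be
#'   shorter than a typical interbeat interval.
#' @param dicrotic_width_frac dicrotic sigma as a multiple of the
#'   systolic sigma (the reflected wave is broader).
#' @return List of class `pulse_shape_params`.
#' @export
pulse_shape_params <- function(systolic_amp = 1, systolic_width = 0.10,
                               dicrotic_amp_frac = 0.3, dicrotic_delay = 0.25,
                               dicrotic_width_frac = 1.3) {
  stopifnot(systolic_amp >= 0, systolic_width > 0,
            dicrotic_amp_frac >= 0, dicrotic_amp_frac <= 1,
            dicrotic_delay > 0)
  structure(list(systolic_amp = systolic_amp, systolic_width = systolic_width,
                 dicrotic_amp_frac = dicrotic_amp_frac,
                 dicrotic_delay = dicrotic_delay,
                 dicrotic_width_frac = dicrotic_width_frac),
            class = "pulse_shape_params")
}

#' Respiratory modulation parameters
#'
#' Respiration imprints on a PPG through three mechanisms: baseline
#' wander (tissue blood volume), amplitude modulation (stroke volume)
#' and frequency modulation (respiratory sinus arrhythmia). All three
#' are modelled as sinusoids at the respiratory frequency.
#'
#' @param rr_brpm respiration rate, breaths per minute (4--60).
#' @param bw_depth baseline wander amplitude, same units as the pulse.
#' @param am_depth amplitude modulation depth, fraction of pulse
#'   amplitude.
#' @param fm_depth frequency modulation depth, fraction of the mean
#'   interbeat interval (RSA).
#' @return List of class `resp_modulation_params`.
#' @export
resp_modulation_params <- function(rr_brpm = 15, bw_depth = 0.3,
                                   am_depth = 0.1, fm_depth = 0.05) {
  stopifnot(rr_brpm >= 4, rr_brpm <= 60,
            bw_depth >= 0, am_depth >= 0, fm_depth >= 0)
  structure(list(rr_brpm = rr_brpm, bw_depth = bw_depth,
                 am_depth = am_depth, fm_depth = fm_depth),
            class = "resp_modulation_params")
}

#' Heart-rate variability parameters for the IBI generator
#'
#' @param hr_mean_bpm mean heart rate, beats per minute (30--180).
#' @param jitter_sd_ms standard deviation of white interbeat-interval
#'   jitter, in ms.
#' @param lf_amp_ms amplitude of a slow deterministic IBI oscillation
#'   (e.g. baroreflex-band), in ms.
#' @param lf_freq_hz frequency of that slow oscillation, Hz.
#' @return List of class `hrv_params`.
#' @export
hrv_params <- function(hr_mean_bpm = 70, jitter_sd_ms = 30,
                       lf_amp_ms = 15, lf_freq_hz = 0.095) {
  stopifnot(hr_mean_bpm >= 30, hr_mean_bpm <= 180, jitter_sd_ms >= 0,
            lf_amp_ms >= 0, lf_freq_hz >= 0)
  structure(list(hr_mean_bpm = hr_mean_bpm, jitter_sd_ms = jitter_sd_ms,
                 lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz),
            class = "hrv_params")
}

#' Generate a ground-truth interbeat-interval series
#'
#' IBIs follow
#' `ibi_k = mean_ibi * (1 + fm_depth * sin(2 pi f_resp t_k)) +
#'  lf_amp * sin(2 pi f_lf t_k) + eps_k`, with `eps_k ~ N(0, jitter_sd^2)`
#' and beat times the cumulative sums. Frequency modulation at the
#' respiratory frequency is the RSA mechanism exploited later by the
#' frequency-modulation respiration-rate estimator.
#'
#' @param hrv an [hrv_params()] object.
#' @param resp a [resp_modulation_params()] object.
#' @param n_beats number of beats (>= 2).
#' @param seed integer seed; all randomness is local to the call.
#' @param t_start time of the first beat in seconds.
#' @return List with `beat_times` (seconds, length `n_beats`) and
#'   `ibis_ms` (length `n_beats - 1`).
#' @export
#' @examples
#' g <- generate_ibis(hrv_params(60, jitter_sd_ms = 0, lf_amp_ms = 0),
#'                    resp_modulation_params(fm_depth = 0), n_beats = 5, seed = 1)
#' g$ibis_ms  # exactly 1000 1000 1000 1000
generate_ibis <- function(hrv, resp, n_beats, seed = 1, t_start = 0.5) {
  stopifnot(n_beats >= 2)
  mean_ibi_s <- 60 / hrv$hr_mean_bpm
  f_resp <- resp$rr_brpm / 60
  eps <- local_rng(seed, stats::rnorm(n_beats - 1, 0, hrv$jitter_sd_ms / 1000))
  beat_times <- numeric(n_beats)
  ibis_s <- numeric(n_beats - 1)
  t <- t_start
  for (k in seq_len(n_beats)) {
    beat_times[k] <- t
    if (k == n_beats) break
    ibi <- mean_ibi_s * (1 + resp$fm_depth * sin(2 * pi * f_resp * t)) +
      (hrv$lf_amp_ms / 1000) * sin(2 * pi * hrv$lf_freq_hz * t) + eps[k]
    if (ibi <= 0) stop("nonphysiological IBI")
    ibis_s[k] <- ibi
    t <- t + ibi
  }
  list(beat_times = beat_times, ibis_ms = ibis_s * 1000)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the global
# RNG state is untouched (no global random state anywhere).
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a PPG waveform from beat times
#'
#' Places one systolic + dicrotic Gaussian complex per beat, applies
#' respiratory amplitude modulation to the pulsatile component, adds
#' respiratory baseline wander and white noise. The truth beat time is
#' the systolic bump apex.
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param pulse a [pulse_shape_params()] object.
#' @param resp a [resp_modulation_params()] object.
#' @param noise_sd white noise standard deviation, arbitrary units.
#' @param fs sampling rate in Hz (>= 20; the device class is
#'   configurable between 20 and 95 Hz).
#' @param seed integer seed for the noise draw.
#' @param duration_s total rendered duration; defaults to the last beat
#'   time plus one second.
#' @return A `ppg_waveform` starting at t = 0.
#' @export
render_ppg <- function(beat_times, pulse = pulse_shape_params(),
                       resp = resp_modulation_params(), noise_sd = 0,
                       fs = 86, seed = 1, duration_s = NULL) {
  stopifnot(fs >= 20)
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing")
  if (is.null(duration_s))
    duration_s <- if (length(beat_times)) max(beat_times) + 1 else 1
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  puls <- numeric(n)
  sw <- pulse$systolic_width
  dw <- pulse$systolic_width * pulse$dicrotic_width_frac
  # The dicrotic bump pulls the apex of the composite complex slightly
  # past the systolic bump center; shift bump placement so the rendered
  # apex falls exactly on the truth beat time.
  shift <- complex_apex_offset(pulse)
  beat_times <- beat_times - shift
  for (b in beat_times) {
    # systolic bump, local support only
    i <- which_range(t, b - 5 * sw, b + 5 * sw, fs)
    puls[i] <- puls[i] + pulse$systolic_amp * exp(-(t[i] - b)^2 / (2 * sw^2))
    d <- b + pulse$dicrotic_delay
    j <- which_range(t, d - 5 * dw, d + 5 * dw, fs)
    puls[j] <- puls[j] +
      pulse$systolic_amp * pulse$dicrotic_amp_frac * exp(-(t[j] - d)^2 / (2 * dw^2))
  }
  f_resp <- resp$rr_brpm / 60
  x <- puls * (1 + resp$am_depth * sin(2 * pi * f_resp * t)) +
    resp$bw_depth * sin(2 * pi * f_resp * t)
  if (noise_sd > 0)
    x <- x + local_rng(seed, stats::rnorm(n, 0, noise_sd))
  waveform(x, fs = fs, t0 = 0, label = "ir")
}

# Apex offset of one systolic+dicrotic complex relative to the
# systolic bump center, found on a 0.1 ms grid.
complex_apex_offset <- function(pulse) {
  sw <- pulse$systolic_width
  dw <- sw * pulse$dicrotic_width_frac
  tt <- seq(-sw, sw, by = 1e-4)
  y <- exp(-tt^2 / (2 * sw^2)) +
    pulse$dicrotic_amp_frac * exp(-(tt - pulse$dicrotic_delay)^2 / (2 * dw^2))
  tt[which.max(y)]
}

# Integer index range of t in [a, b] without scanning the whole vector.
which_range <- function(t, a, b, fs) {
  n <- length(t)
  i0 <- max(1L, floor(a * fs) + 1L)
  i1 <- min(n, ceiling(b * fs) + 1L)
  if (i1 < i0) integer(0) else i0:i1
}

#' Inject a motion-artifact transient and matching motion trace
#'
#' Adds a high-variance random-walk transient to the PPG over
#' `[start, start + dur)` and returns a 10 Hz motion-magnitude trace
#' that is flat at baseline except for an elevated segment over the
#' same interval — emulating the subtle arm movements that corrupt
#' wrist PPG recordings.
#'
#' @param w a `ppg_waveform`.
#' @param start,dur artifact start time and duration in seconds; must
#'   lie within the waveform.
#' @param scale artifact amplitude in signal units (the random walk is
#'   normalized to unit standard deviation and multiplied by `scale`).
#' @param seed integer seed.
#' @param motion_fs motion trace sampling rate in Hz.
#' @return List with elements `waveform` (corrupted copy) and `motion`
#'   (a `ppg_motion`).
#' @export
inject_motion <- function(w, start, dur, scale, seed = 1, motion_fs = 10) {
  if (start < w$t0 || start + dur > w$t0 + duration(w))
    stop("artifact segment out of waveform range")
  n <- length(w$values)
  i0 <- round((start - w$t0) * w$fs) + 1L
  i1 <- min(n, i0 + round(dur * w$fs) - 1L)
  x <- w$values
  nm <- round(duration(w) * motion_fs)
  mag <- rep(0.02, nm)
  if (scale > 0 && i1 >= i0) {
    k <- i1 - i0 + 1L
    draws <- local_rng(seed, list(walk = stats::rnorm(k),
                                  mot = abs(stats::rnorm(nm))))
    walk <- cumsum(draws$walk)
    walk <- walk - mean(walk)
    s <- stats::sd(walk)
    if (s > 0) walk <- walk / s
    x[i0:i1] <- x[i0:i1] + scale * walk
    tm <- w$t0 + (seq_len(nm) - 1) / motion_fs
    inside <- tm >= start & tm < start + dur
    mag[inside] <- 0.02 + scale * (0.3 + 0.2 * draws$mot[inside])
  }
  list(waveform = waveform(x, fs = w$fs, t0 = w$t0, label = w$label),
       motion = motion_trace(mag, fs = motion_fs, t0 = w$t0))
}

#' Per-window ground-truth metrics from generated IBIs
#'
#' Applies the package's own estimator definitions ([hr_bpm()],
#' [sdnn_ms()], [rmssd_ms()]) directly to the noiseless generated IBI
#' series, window by window. An IBI is assigned to the window that
#' contains the beat starting it, the same convention the pipeline
#' uses.
#'
#' @param beat_times truth beat times in seconds.
#' @param ibis_ms truth IBIs in ms.
#' @param rr_brpm true respiration rate (constant per session).
#' @param duration_s total recording duration in seconds.
#' @param window_s window duration in seconds.
#' @return Data frame with one row per complete window: `index`,
#'   `start`, `hr_bpm`, `sdnn_ms`, `rmssd_ms`, `rr_brpm`, `n_beats`.
#' @export
window_truth <- function(beat_times, ibis_ms, rr_brpm, duration_s,
                         window_s = 60) {
  k <- floor(duration_s / window_s)
  starts <- (seq_len(k) - 1) * window_s
  t_ibi <- beat_times[-length(beat_times)]  # start beat of each IBI
  rows <- lapply(seq_len(k), function(i) {
    inw <- t_ibi >= starts[i] & t_ibi < starts[i] + window_s
    ib <- ibis_ms[inw]
    data.frame(index = i - 1L, start = starts[i],
               hr_bpm = if (length(ib)) hr_bpm(ib) else NA_real_,
               sdnn_ms = sdnn_ms(ib), rmssd_ms = rmssd_ms(ib),
               rr_brpm = rr_brpm, n_beats = sum(inw))
  })
  do.call(rbind, rows)
}

#' One synthetic study session under the validation-cohort conditions
#'
#' Draws a virtual subject's physiological parameters deterministically
#' from the seed — heart rate 55--95 bpm, white IBI jitter 15--55 ms,
#' slow IBI oscillation 5--25 ms, RSA depth 0.02--0.08, respiration
#' rate 8--20 breaths per minute — and renders a 3-minute session,
#' optionally with white noise at a prescribed pulse-power
#' signal-to-noise ratio. These ranges span a resting adult cohort and
#' are the fixed conditions under which parameter-recovery performance
#' is assessed.
#'
#' @param seed integer; determines both the subject parameters and all
#'   within-session randomness.
#' @param snr pulse-power to noise-power ratio; `NA` renders a
#'   noise-free session.
#' @param duration_s session length in seconds.
#' @return A [simulate_session()] result.
#' @export
cohort_session <- function(seed, snr = NA, duration_s = 180) {
  par <- local_rng(seed * 7919 + 1, list(
    hr = stats::runif(1, 55, 95),
    jitter = stats::runif(1, 15, 55),
    lf = stats::runif(1, 5, 25),
    fm = stats::runif(1, 0.02, 0.08),
    rr = stats::runif(1, 8, 20)))
  s <- simulate_session(
    hrv = hrv_params(par$hr, par$jitter, par$lf, 0.095),
    resp = resp_modulation_params(par$rr, bw_depth = 0.3, am_depth = 0.1,
                                  fm_depth = par$fm),
    duration_s = duration_s, noise_sd = 0, seed = seed)
  if (!is.na(snr)) {
    x <- s$ppg$values
    noise_sd <- sqrt(mean((x - mean(x))^2) / snr)
    s$ppg$values <- x +
      local_rng(seed * 7919 + 2, stats::rnorm(length(x), 0, noise_sd))
  }
  s
}

#' Simulate one wristband recording session with ground truth
#'
#' Convenience wrapper: draws an IBI series, renders the PPG, optionally
#' injects a motion artifact, and tabulates per-window truth metrics.
#'
#' @param hrv,resp,pulse parameter objects; see [hrv_params()],
#'   [resp_modulation_params()], [pulse_shape_params()].
#' @param duration_s session length in seconds (device tests typically
#'   run 2--4 minutes).
#' @param noise_sd white noise standard deviation.
#' @param fs PPG sampling rate in Hz.
#' @param motion `NULL` for none, or `list(start =, dur =, scale =)`.
#' @param window_s window duration for the truth table.
#' @param seed integer seed controlling every random draw in the
#'   session.
#' @return List with `ppg` (`ppg_waveform`), `motion` (`ppg_motion` or
#'   `NULL`) and `truth` (list: `beat_times`, `ibis_ms`, `rr_brpm`,
#'   `window_truth` data frame).
#' @export
simulate_session <- function(hrv = hrv_params(), resp = resp_modulation_params(),
                             pulse = pulse_shape_params(), duration_s = 180,
                             noise_sd = 0, fs = 86, motion = NULL,
                             window_s = 60, seed = 1) {
  n_beats <- ceiling(duration_s * hrv$hr_mean_bpm / 60) + 5L
  gen <- generate_ibis(hrv, resp, n_beats, seed = seed)
  keep <- gen$beat_times <= duration_s - 0.5
  beat_times <- gen$beat_times[keep]
  ibis_ms <- gen$ibis_ms[seq_len(max(0L, sum(keep) - 1L))]
  ppg <- render_ppg(beat_times, pulse = pulse, resp = resp,
                    noise_sd = noise_sd, fs = fs, seed = seed + 1L,
                    duration_s = duration_s)
  mot <- NULL
  if (!is.null(motion)) {
    inj <- inject_motion(ppg, motion$start, motion$dur, motion$scale,
                         seed = seed + 2L)
    ppg <- inj$waveform
    mot <- inj$motion
  }
  truth <- list(beat_times = beat_times, ibis_ms = ibis_ms,
                rr_brpm = resp$rr_brpm,
                window_truth = window_truth(beat_times, ibis_ms,
                                            resp$rr_brpm, duration_s,
                                            window_s))
  list(ppg = ppg, motion = mot, truth = truth)
}
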