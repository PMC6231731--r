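# Shared fixture builders: every fixture is generated in code at test
# time with an explicit seed.

quiet_session <- function(duration_s = 120, noise_sd = 0, seed = 1,
                          hr = 70, jitter = 30, rr = 15, fm = 0.05,
                          bw = 0.3, am = 0.1, lf = 15, motion = NULL) {
  simulate_session(
    hrv = hrv_params(hr, jitter, lf, 0.095),
    resp = resp_modulation_params(rr, bw, am, fm),
    duration_s = duration_s, noise_sd = noise_sd, seed = seed,
    motion = motion)
}

# Sinusoid waveform helper
sine_wave <- function(freq, fs = 86, dur = 60, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  waveform(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

# noise sd giving pulse-power SNR `snr` for a rendered clean session
noise_for_snr <- function(clean_ppg, snr) {
  x <- clean_ppg$values
  sqrt(mean((x - mean(x))^2) / snr)
}

# Brute-force reimplementation of the log-MAD ectopic rule, kept
# deliberately independent of remove_outliers() internals.
oracle_mad_removal <- function(ibis, ref, threshold = 6.25) {
  lg <- sort(log(ref))
  n <- length(lg)
  med <- if (n %% 2 == 1) lg[(n + 1) / 2] else (lg[n / 2] + lg[n / 2 + 1]) / 2
  devs <- sort(abs(log(ref) - med))
  mad0 <- if (n %% 2 == 1) devs[(n + 1) / 2] else
    (devs[n / 2] + devs[n / 2 + 1]) / 2
  which(abs(log(ibis) - med) > threshold * mad0)
}
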