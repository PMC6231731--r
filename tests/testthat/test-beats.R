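test_that("parabolic refinement recovers known vertices", {
  fs <- 86
  # symmetric samples: vertex exactly on the grid point
  w <- waveform(c(0, 1.0, 2.0, 1.0, 0), fs)
  expect_equal(as.numeric(refine_onset(w, 3)), 2 / fs, tolerance = 1e-12)

  # known parabola with vertex at idx + 0.3 samples
  idx <- 5
  x <- seq_len(9)
  y <- -(x - (idx + 0.3))^2 + 4
  t_ref <- refine_onset(waveform(y, fs), idx)
  expect_equal(as.numeric(t_ref), (idx - 1 + 0.3) / fs, tolerance = 1e-9)
  expect_true(attr(t_ref, "refined"))

  # sampled sinusoid: refined apex within 1 ms of the analytic apex
  t <- seq(0, 2, by = 1 / fs)
  y <- sin(2 * pi * 1.2 * t)
  apex_true <- 1 / (4 * 1.2)
  i <- which.max(y[t < 0.5])
  expect_lt(abs(as.numeric(refine_onset(waveform(y, fs), i)) - apex_true),
            1e-3)

  # boundary sample: unrefined, flagged
  t_b <- refine_onset(waveform(c(2, 1, 0), fs), 1)
  expect_false(attr(t_b, "refined"))
  expect_equal(as.numeric(t_b), 0)
})

test_that("CWT candidates cover every truth apex on clean signals", {
  s <- quiet_session(duration_s = 62, seed = 31, hr = 60, jitter = 20)
  xb <- bandpass(s$ppg)
  cand <- detect_peaks_cwt(xb)
  expect_gte(length(cand), 59)
  truth_idx <- round(s$truth$beat_times * 86) + 1
  for (ti in truth_idx)
    expect_true(min(abs(cand - ti)) <= 1)

  expect_length(detect_peaks_cwt(waveform(rep(0, 86 * 10), 86)), 0)
})

test_that("CWT candidate recall survives moderate noise", {
  s <- quiet_session(duration_s = 62, seed = 32, hr = 60, jitter = 20)
  noisy <- s$ppg
  set.seed(132)
  noisy$values <- noisy$values +
    stats::rnorm(length(noisy$values), sd = noise_for_snr(s$ppg, 10))
  xb <- bandpass(noisy)
  cand <- detect_peaks_cwt(xb)
  truth_idx <- round(s$truth$beat_times * 86) + 1
  hits <- vapply(truth_idx, function(ti) min(abs(cand - ti)) <= 2,
                 logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("onset selection prunes close spurious candidates by prominence", {
  fs <- 86
  w <- waveform(rep(0, fs * 10), fs)
  truth <- seq(1, 5) * fs + 1L
  spur <- truth + round(0.1 * fs)
  cand <- structure(c(truth, spur),
                    strength = c(rep(1, 5), rep(0.5, 5)))
  sel <- select_onsets(cand, w)
  expect_identical(as.integer(sel), as.integer(truth))

  # brute-force oracle: among all admissible subsets, the selected one
  # has maximal total prominence
  cfg <- beat_config()
  all_c <- c(truth, spur)
  str_c <- c(rep(1, 5), rep(0.5, 5))
  best <- NULL; best_sum <- -Inf
  for (mask in 0:(2^10 - 1)) {
    pick <- which(bitwAnd(mask, 2^(0:9)) > 0)
    if (length(pick) > 1 &&
        min(diff(sort(all_c[pick]))) < cfg$min_ibi_s * fs) next
    if (sum(str_c[pick]) > best_sum) {
      best_sum <- sum(str_c[pick]); best <- sort(all_c[pick])
    }
  }
  expect_identical(as.integer(sel), as.integer(best))

  # permutation stability: discovery order cannot matter
  set.seed(77)
  perm <- sample(seq_along(all_c))
  cand_p <- structure(all_c[perm], strength = str_c[perm])
  expect_identical(as.integer(select_onsets(cand_p, w)),
                   as.integer(sel))

  one <- structure(500L, strength = 1)
  expect_identical(as.integer(select_onsets(one, w)), 500L)
  expect_length(select_onsets(integer(0), w), 0)
})

test_that("candidates at exactly the truth apices are all retained", {
  s <- quiet_session(duration_s = 62, seed = 33, hr = 72)
  xb <- bandpass(s$ppg)
  truth_idx <- as.integer(round(s$truth$beat_times * 86) + 1)
  sel <- select_onsets(structure(truth_idx, strength = rep(1, length(truth_idx))),
                       xb)
  expect_identical(as.integer(sel), truth_idx)
  expect_true(attr(sel, "reliable"))
})

test_that("end-to-end beat recovery on clean signals is sample-accurate", {
  s <- quiet_session(duration_s = 120, seed = 34, hr = 75, jitter = 35)
  xb <- bandpass(s$ppg)
  series <- detect_beats(xb)
  truth <- s$truth$beat_times
  matched <- vapply(truth, function(b)
    series$times[which.min(abs(series$times - b))], numeric(1))
  # every truth beat matched within one sample
  expect_lt(max(abs(matched - truth)), 1 / 86)
  # recovered IBIs match truth IBIs within 1.5 samples per interval
  expect_lt(max(abs(diff(matched) - diff(truth))) , 1.5 / 86)
})

test_that("selection never admits interbeat intervals below the floor", {
  for (seed in 35:37) {
    s <- quiet_session(duration_s = 62, seed = seed,
                       noise_sd = 0.2, hr = 90)
    series <- detect_beats(bandpass(s$ppg))
    if (length(series$times) > 1)
      expect_gte(min(diff(series$times)), beat_config()$min_ibi_s - 0.02)
    ibis <- beats_to_ibis(series)
    if (length(ibis)) {
      expect_gte(min(ibis), beat_config()$min_ibi_s * 1000)
      expect_lte(max(ibis), beat_config()$max_ibi_s * 1000)
    }
  }
})

test_that("beat qualification accepts clean beats and needs a template", {
  s <- quiet_session(duration_s = 62, seed = 38)
  xb <- bandpass(s$ppg)
  series <- qualify_beats(detect_beats(xb), xb)
  expect_true(all(series$quality))

  few <- series
  few$times <- few$times[1:2]
  few$onset_times <- few$onset_times[1:2]
  few$ibis_ms <- diff(few$times) * 1000
  few$quality <- few$quality[1:2]
  expect_false(any(qualify_beats(few, xb)$quality))
})

test_that("beats overlapping a motion transient are disqualified", {
  s <- quiet_session(duration_s = 120, seed = 39,
                     motion = list(start = 70, dur = 8, scale = 5))
  xb <- bandpass(s$ppg)
  series <- qualify_beats(detect_beats(xb), xb, s$motion)
  sup_end <- c(series$onset_times[-1],
               max(series$times) + stats::median(diff(series$times)))
  overlap <- sup_end > 70 & series$onset_times < 78
  # all overlapping beats disqualified
  expect_true(all(!series$quality[overlap]))
  # beats clear of the artifact's filtered footprint stay qualified
  clear <- sup_end < 68 | series$onset_times > 80
  expect_true(all(series$quality[clear]))
})

test_that("IBIs survive only between qualified adjacent beats", {
  mk <- function(times, quality) {
    structure(list(times = times, onset_times = times - 0.2,
                   ibis_ms = diff(times) * 1000, quality = quality,
                   amplitude = rep(1, length(times)),
                   rise_time_s = rep(0.2, length(times)), fs = 86),
              class = "beat_series")
  }
  expect_equal(beats_to_ibis(mk(c(0, 1, 2), rep(TRUE, 3))), c(1000, 1000))
  expect_length(beats_to_ibis(mk(c(0, 1, 2), c(TRUE, FALSE, TRUE))), 0)

  # exhaustive check on 5 onsets with one unqualified
  times <- c(0, 0.9, 1.8, 2.8, 3.7)
  for (bad in 1:5) {
    q <- rep(TRUE, 5); q[bad] <- FALSE
    got <- beats_to_ibis(mk(times, q))
    expected <- unlist(lapply(1:4, function(k)
      if (q[k] && q[k + 1]) (times[k + 1] - times[k]) * 1000 else NULL))
    if (is.null(expected)) expected <- numeric(0)
    expect_equal(got, as.numeric(expected))
  }
})
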