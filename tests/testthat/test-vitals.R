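test_that("the log-MAD rule removes exactly the ectopic interval", {
  set.seed(201)
  ibis <- c(rnorm(30, 800, 30), 2400)
  res <- remove_outliers(ibis)
  expect_identical(res$removed, 31L)
  expect_identical(res$removed, oracle_mad_removal(ibis, ibis))
  expect_equal(res$kept, ibis[-31])
  expect_false(res$mad_zero_fallback)
})

test_that("MAD-zero fallback and infinite threshold behave", {
  same <- rep(800, 20)
  res <- remove_outliers(same)
  expect_length(res$removed, 0)
  expect_true(res$mad_zero_fallback)
  # fallback still rejects a >1.5x deviation
  res2 <- remove_outliers(c(rep(800, 20), 2400), ref_ibis_ms = rep(800, 20))
  expect_identical(res2$removed, 21L)

  set.seed(202)
  ibis <- rnorm(40, 800, 60)
  res3 <- remove_outliers(ibis, outlier_config(mad_threshold = Inf))
  expect_identical(res3$kept, ibis)
})

test_that("outlier removal is idempotent and honours recording-level stats", {
  set.seed(203)
  rec <- c(rnorm(120, 850, 40), 2600, 250)
  first <- remove_outliers(rec)
  second <- remove_outliers(first$kept)
  expect_length(second$removed, 0)

  # window IBIs judged against the full-recording statistics
  win <- rec[1:10]
  res <- remove_outliers(win, ref_ibis_ms = rec)
  expect_identical(res$removed, oracle_mad_removal(win, rec))
})

test_that("HR, SDNN and RMSSD reproduce their closed forms", {
  expect_equal(hr_bpm(rep(1000, 10)), 60)
  expect_equal(hr_bpm(rep(500, 10)), 120)
  expect_equal(hr_bpm(c(800, 850, 900)), 60000 / 850)

  expect_equal(sdnn_ms(rep(777, 5)), 0)
  expect_equal(sdnn_ms(c(750, 850)), sqrt(2 * 50^2 / 1), tolerance = 1e-12)
  expect_equal(rmssd_ms(rep(777, 5)), 0)
  expect_equal(rmssd_ms(rep(c(750, 850), 25)), 100)
  expect_true(is.na(sdnn_ms(1000)))
  expect_true(is.na(rmssd_ms(1000)))
  expect_true(is.na(hr_bpm(numeric(0))))

  set.seed(204)
  x <- rnorm(2000, 800, 40)
  expect_lt(abs(sdnn_ms(x) - 40), 2)
})

test_that("HRV measures are translation invariant and scale equivariant", {
  set.seed(205)
  x <- rnorm(50, 900, 35)
  expect_equal(sdnn_ms(x + 200), sdnn_ms(x))
  expect_equal(rmssd_ms(x + 200), rmssd_ms(x))
  expect_equal(sdnn_ms(2 * x), 2 * sdnn_ms(x))
  expect_equal(rmssd_ms(2 * x), 2 * rmssd_ms(x))
  expect_equal(sdnn_ms(rep(800, 10), population = TRUE), 0)
})

test_that("baseline-wander method reads the breathing rate off the drift", {
  t <- seq(0, 60 - 1 / 86, by = 1 / 86)
  w <- waveform(0.4 * sin(2 * pi * 0.2 * t), fs = 86)
  res <- rr_baseline_wander(w)
  expect_equal(res$rr_brpm, 12, tolerance = 0.5)
  expect_gt(res$quality, 0.5)

  # 0.25 Hz modulation carried on a full synthetic session
  s <- quiet_session(duration_s = 60, seed = 206, rr = 15)
  res2 <- rr_baseline_wander(s$ppg)
  expect_equal(res2$rr_brpm, 15, tolerance = 1)

  # nothing to detect without baseline wander
  s0 <- quiet_session(duration_s = 60, seed = 207, bw = 0, am = 0, fm = 0,
                      jitter = 20)
  res0 <- rr_baseline_wander(s0$ppg)
  expect_true(is.null(res0) || res0$quality < 0.5)
})

test_that("frequency-modulation method traces the RSA ridge", {
  mk <- function(rr, fm, jitter, seed) {
    g <- generate_ibis(hrv_params(70, jitter, lf_amp_ms = 0),
                       resp_modulation_params(rr_brpm = rr, fm_depth = fm),
                       n_beats = 75, seed = seed)
    rr_frequency_modulation(g$beat_times[-length(g$beat_times)], g$ibis_ms)
  }
  res <- mk(15, 0.05, 0, 301)
  expect_equal(res$rr_brpm, 15, tolerance = 0.5)
  expect_gt(res$quality, 0.5)

  res6 <- mk(6, 0.05, 0, 302)
  expect_equal(res6$rr_brpm, 6, tolerance = 1)

  # unmodulated jittery IBIs: no credible ridge
  res0 <- mk(15, 0, 30, 303)
  expect_true(is.null(res0) || res0$quality < 0.5)
})

test_that("respiration fusion follows its qualification rules", {
  cfg <- vitals_config()
  expect_equal(rr_fuse(list(rr_brpm = 12, quality = 0.9),
                       list(rr_brpm = 12.5, quality = 0.8), cfg),
               (12 * 0.9 + 12.5 * 0.8) / 1.7, tolerance = 1e-12)
  expect_true(is.na(rr_fuse(list(rr_brpm = 12, quality = 0.9),
                            list(rr_brpm = 20, quality = 0.8), cfg)))
  expect_equal(rr_fuse(NULL, list(rr_brpm = 15, quality = 0.8), cfg), 15)
  expect_equal(rr_fuse(list(rr_brpm = 11, quality = 0.7),
                       list(rr_brpm = 14, quality = 0.2), cfg), 11)
  expect_true(is.na(rr_fuse(NULL, NULL, cfg)))

  # fused estimates never leave the respiratory band
  set.seed(208)
  for (i in 1:50) {
    bw <- list(rr_brpm = runif(1, 6, 30), quality = runif(1))
    fm <- list(rr_brpm = runif(1, 6, 30), quality = runif(1))
    out <- rr_fuse(bw, fm, cfg)
    if (!is.na(out)) {
      expect_gte(out, 6)
      expect_lte(out, 30)
    }
  }
})

test_that("window metrics run end to end on a clean recording", {
  s <- quiet_session(duration_s = 240, seed = 209)
  wm <- compute_window_metrics(s$ppg)
  expect_equal(nrow(wm), 4)
  expect_true(all(wm$qualified))
  expect_true(all(wm$valid_hr & wm$valid_sdnn & wm$valid_rmssd & wm$valid_rr))
  tr <- s$truth$window_truth
  expect_lt(max(abs(wm$hr_bpm - tr$hr_bpm)), 0.3)
})

test_that("a motion-corrupted window is gated out, the rest survive", {
  s <- quiet_session(duration_s = 180, seed = 210,
                     motion = list(start = 80, dur = 15, scale = 5))
  wm <- compute_window_metrics(s$ppg, s$motion)
  expect_false(wm$qualified[2])
  expect_true(all(is.na(wm$hr_bpm[2])))
  expect_true(all(wm$qualified[c(1, 3)]))
  expect_true(all(wm$valid_hr[c(1, 3)]))
})

test_that("an empty or too-short recording yields an empty metrics table", {
  short <- waveform(rnorm(86 * 30), fs = 86)
  wm <- compute_window_metrics(short, window_s = 60)
  expect_equal(nrow(wm), 0)
  expect_s3_class(wm, "window_metrics")
})
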