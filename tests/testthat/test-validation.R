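test_that("beat-series alignment recovers known offsets", {
  g <- generate_ibis(hrv_params(70, 40), resp_modulation_params(), 120,
                     seed = 401)
  bt <- g$beat_times
  expect_equal(as.numeric(align_beats(bt + 3, bt)), -3, tolerance = 0.25)
  expect_equal(as.numeric(align_beats(bt, bt)), 0, tolerance = 0.25)

  # unrelated series cannot align
  g2 <- generate_ibis(hrv_params(64, 45), resp_modulation_params(), 120,
                      seed = 402)
  expect_error(align_beats(g2$beat_times, bt), "alignment failed")
  expect_error(align_beats(bt[1:5], bt), "at least 10")
})

test_that("error metrics match hand arithmetic", {
  em <- error_metrics(data.frame(test = c(60, 70, 80), ref = c(61, 69, 80)))
  expect_equal(em$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(em$me, 0)
  expect_equal(em$n, 3)

  single <- error_metrics(data.frame(test = 100, ref = 90))
  expect_equal(single$mae, 10)
  expect_equal(single$mape, 100 * 10 / 90, tolerance = 1e-12)
  expect_equal(single$me, 10)

  same <- error_metrics(data.frame(test = c(5, 6), ref = c(5, 6)))
  expect_equal(same$mae, 0)
  expect_equal(same$mape, 0)
  expect_equal(same$me, 0)

  expect_warning(error_metrics(data.frame(test = c(1, 2), ref = c(1, 0))),
                 "zero reference")
})

test_that("error metrics are MAE-symmetric and ME-antisymmetric under swap", {
  set.seed(403)
  a <- rnorm(20, 70, 5); b <- a + rnorm(20)
  fwd <- error_metrics(data.frame(test = a, ref = b))
  rev <- error_metrics(data.frame(test = b, ref = a))
  expect_equal(fwd$mae, rev$mae)
  expect_equal(fwd$me, -rev$me)
})

test_that("Pearson correlation matches a hand-computed table and is affine invariant", {
  expect_equal(pearson_r(data.frame(test = 1:5, ref = 1:5)), 1)
  expect_equal(pearson_r(data.frame(test = 1:5, ref = -(1:5) + 7)), -1)
  # frozen from the explicit product-moment formula on this table
  p <- data.frame(test = c(60, 70, 80, 65, 75), ref = c(62, 69, 81, 66, 73))
  expect_equal(pearson_r(p), 0.9801153942, tolerance = 1e-8)
  expect_equal(pearson_r(data.frame(test = 3 * p$test + 11, ref = p$ref)),
               pearson_r(p), tolerance = 1e-12)
  expect_error(pearson_r(data.frame(test = c(1, 1, 1), ref = 1:3)),
               "zero variance")
  expect_error(pearson_r(data.frame(test = 1:2, ref = 1:2)), "3 pairs")
})

test_that("simple Bland-Altman reproduces the classic formula", {
  p <- data.frame(test = c(10, 11, 12) - c(1, 0, -1), ref = c(10, 11, 12),
                  subject = c("a", "b", "c"))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$ba_ratio, 1.96 / mean((p$test + p$ref) / 2),
               tolerance = 1e-12)

  zero <- bland_altman(data.frame(test = c(5, 5), ref = c(5, 5)))
  expect_equal(zero$bias, 0)
  expect_equal(zero$sd_diff, 0)
  expect_equal(zero$ba_ratio, 0)

  # one observation per subject: repeated-measures mode collapses to classic
  set.seed(404)
  q <- data.frame(test = rnorm(8, 100, 4), ref = rnorm(8, 100, 4),
                  subject = letters[1:8])
  expect_equal(bland_altman(q, repeated_measures = TRUE)$sd_diff,
               bland_altman(q)$sd_diff, tolerance = 1e-12)
})

test_that("repeated-measures SD combines the variance components", {
  # 2 subjects x 3 repeats constructed for within-variance 1 and
  # between-variance 4: sd_diff must be sqrt(5)
  c0 <- sqrt(26 / 12)
  d <- c(c0 + c(-1, 0, 1), -c0 + c(-1, 0, 1))
  p <- data.frame(test = 100 + d, ref = 100,
                  subject = rep(c("a", "b"), each = 3))
  ba <- bland_altman(p, repeated_measures = TRUE)
  expect_equal(ba$sd_diff, sqrt(5), tolerance = 1e-6)
  expect_equal(ba$n_subjects, 2)
  expect_equal(ba$n_pairs, 6)

  expect_warning(
    one <- bland_altman(data.frame(test = c(1, 2, 3), ref = 0,
                                   subject = "a"),
                        repeated_measures = TRUE),
    "single subject")
  expect_equal(one$sd_diff, 1)
})

test_that("bilateral agreement reports per-metric absolute differences", {
  s <- quiet_session(duration_s = 180, seed = 405)
  wm <- compute_window_metrics(s$ppg)
  expect_equal(bilateral_agreement(wm, wm)$mean_abs_diff, rep(0, 4))

  shifted <- wm
  shifted$hr_bpm <- shifted$hr_bpm + 1
  res <- bilateral_agreement(wm, shifted, metrics = "hr_bpm")
  expect_equal(res$mean_abs_diff, 1)
  expect_equal(res$sd_abs_diff, 0)

  invalid <- wm
  invalid$hr_bpm <- NA_real_
  expect_equal(nrow(bilateral_agreement(wm, invalid, metrics = "hr_bpm")), 0)
})

test_that("two renderings of the same truth agree closely in HR", {
  g <- generate_ibis(hrv_params(72, 35), resp_modulation_params(), 220,
                     seed = 406)
  mk <- function(seed) {
    w <- render_ppg(g$beat_times, noise_sd = 0.1, seed = seed,
                    duration_s = 180)
    compute_window_metrics(w)
  }
  left <- mk(1); right <- mk(2)
  res <- bilateral_agreement(left, right, metrics = "hr_bpm")
  expect_gt(res$n, 0)
  expect_lt(res$mean_abs_diff, 1)
})

test_that("window sensitivity produces one row per duration and metric", {
  sessions <- list(quiet_session(duration_s = 120, seed = 407))
  tab <- window_sensitivity(sessions, durations = 60, metrics = c("hr", "rr"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$duration_s, c(60, 60))
  expect_true(all(tab$n >= 1))
})
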