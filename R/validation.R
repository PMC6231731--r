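# Method-comparison statistics for device validation: beat-series
# alignment, error metrics, Pearson correlation, Bland-Altman limits of
# agreement (with the repeated-measures variance-components
# correction), bilateral (left/right) agreement, and window-duration
# sensitivity re-analysis.

#' Align a test beat series to a reference by cross-correlation
#'
#' Both interbeat-interval series are turned into IBI-versus-time step
#' functions, sampled on a common uniform grid, and the time offset
#' maximizing their Pearson correlation over `±max_lag` is returned
#' (search granularity 0.25 s). Absorbs clock offset and pulse transit
#' time into one free parameter.
#'
#' @param test_times,ref_times beat times in seconds (>= 10 beats
#'   each).
#' @param max_lag maximum |offset| searched, seconds.
#' @param step search granularity, seconds.
#' @param grid_hz sampling rate of the step-function grid.
#' @return Offset in seconds (add to the test times), with attribute
#'   `"correlation"`. Errors with "alignment failed" when the best
#'   correlation is below 0.5.
#' @export
align_beats <- function(test_times, ref_times, max_lag = 10, step = 0.25,
                        grid_hz = 4) {
  if (length(test_times) < 10 || length(ref_times) < 10)
    stop("need at least 10 beats in each series")
  step_fun <- function(times) {
    ib <- diff(times) * 1000
    stats::approxfun(times[-length(times)], ib, method = "constant",
                     rule = 2)
  }
  f_test <- step_fun(test_times)
  f_ref <- step_fun(ref_times)
  offsets <- seq(-max_lag, max_lag, by = step)
  lo <- max(min(ref_times), min(test_times) - max_lag)
  hi <- min(max(ref_times), max(test_times) + max_lag)
  g <- seq(lo, hi, by = 1 / grid_hz)
  yr <- f_ref(g)
  cors <- vapply(offsets, function(d) {
    yt <- f_test(g - d)
    if (stats::sd(yt) == 0 || stats::sd(yr) == 0) return(-1)
    stats::cor(yt, yr)
  }, numeric(1))
  best <- which.max(cors)
  if (cors[best] < 0.5) stop("alignment failed")
  structure(offsets[best], correlation = cors[best])
}

# Coerce (test, ref) inputs: either two vectors or a data frame with
# columns test and ref (plus optional subject).
as_pairs <- function(pairs, ref = NULL) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("test", "ref") %in% names(pairs)))
    return(pairs)
  }
  data.frame(test = pairs, ref = ref)
}

#' Agreement error metrics for paired measurements
#'
#' Mean absolute error, mean absolute percentage error and mean
#' (signed) error between test and reference, with the sample standard
#' deviations of the per-pair quantities. Pairs with a zero reference
#' are excluded from MAPE with a warning.
#'
#' @param pairs data frame with columns `test` and `ref`, or a numeric
#'   vector of test values.
#' @param ref reference values when `pairs` is a vector.
#' @return List with `mae`, `mae_sd`, `mape`, `mape_sd`, `me`, `me_sd`,
#'   `n`.
#' @export
error_metrics <- function(pairs, ref = NULL) {
  p <- as_pairs(pairs, ref)
  stopifnot(nrow(p) >= 1)
  ae <- abs(p$test - p$ref)
  e <- p$test - p$ref
  nz <- p$ref != 0
  if (any(!nz)) warning("pairs with zero reference excluded from MAPE")
  ape <- 100 * ae[nz] / abs(p$ref[nz])
  list(mae = mean(ae), mae_sd = if (length(ae) > 1) stats::sd(ae) else NA_real_,
       mape = if (any(nz)) mean(ape) else NA_real_,
       mape_sd = if (sum(nz) > 1) stats::sd(ape) else NA_real_,
       me = mean(e), me_sd = if (length(e) > 1) stats::sd(e) else NA_real_,
       n = nrow(p))
}

#' Pearson correlation of paired measurements
#'
#' @inheritParams error_metrics
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(pairs, ref = NULL) {
  p <- as_pairs(pairs, ref)
  if (nrow(p) < 3) stop("need at least 3 pairs")
  if (stats::sd(p$test) == 0 || stats::sd(p$ref) == 0)
    stop("zero variance")
  stats::cor(p$test, p$ref)
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean test-minus-reference difference; the limits of
#' agreement are `bias ± 1.96 sd_diff`. With
#' `repeated_measures = TRUE` multiple observations per subject are
#' handled by the variance-components correction: a one-way ANOVA of
#' the differences on subject gives
#' `sd_diff^2 = sigma2_between + sigma2_within` with
#' `sigma2_within = MSW` and
#' `sigma2_between = (MSB - MSW) / n0`,
#' `n0 = (N - sum(n_i^2)/N) / (m - 1)` — so that the limits describe
#' the difference for a new observation on a new individual, not the
#' (narrower) spread of the pooled differences. The Bland-Altman ratio
#' is `1.96 sd_diff` divided by the mean of the pairwise means; the 95%
#' CI on the bias uses a t quantile with (subjects - 1) degrees of
#' freedom under repeated measures.
#'
#' @param pairs data frame with columns `test`, `ref`, and `subject`
#'   when `repeated_measures = TRUE`.
#' @param repeated_measures account for multiple windows per subject.
#' @return List of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `ba_ratio`, `ci_bias` (length 2),
#'   `n_pairs`, `n_subjects`.
#' @export
bland_altman <- function(pairs, repeated_measures = FALSE) {
  p <- as_pairs(pairs)
  stopifnot(nrow(p) >= 2)
  d <- p$test - p$ref
  bias <- mean(d)
  n <- length(d)
  if (repeated_measures) {
    stopifnot("subject" %in% names(p))
    subj <- factor(p$subject)
    m <- nlevels(subj)
    ni_all <- as.numeric(table(subj))
    if (max(ni_all) == 1) {
      # one observation per subject: the classic 1986 formula applies
      sd_diff <- stats::sd(d)
      se_bias <- sd_diff / sqrt(n)
      dfree <- n - 1
    } else if (m < 2) {
      warning("single subject; falling back to simple SD")
      sd_diff <- stats::sd(d)
      se_bias <- sd_diff / sqrt(n)
      dfree <- n - 1
    } else {
      fit <- stats::aov(d ~ subj)
      tab <- summary(fit)[[1]]
      msb <- tab["subj", "Mean Sq"]
      msw <- tab["Residuals", "Mean Sq"]
      ni <- as.numeric(table(subj))
      n0 <- (n - sum(ni^2) / n) / (m - 1)
      sigma2_b <- max(0, (msb - msw) / n0)
      sd_diff <- sqrt(sigma2_b + msw)
      subj_means <- tapply(d, subj, mean)
      se_bias <- stats::sd(subj_means) / sqrt(m)
      dfree <- m - 1
    }
    n_subjects <- m
  } else {
    sd_diff <- stats::sd(d)
    se_bias <- sd_diff / sqrt(n)
    dfree <- n - 1
    n_subjects <- if ("subject" %in% names(p))
      length(unique(p$subject)) else n
  }
  mean_means <- mean((p$test + p$ref) / 2)
  tq <- stats::qt(0.975, dfree)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 ba_ratio = abs(1.96 * sd_diff / mean_means),
                 ci_bias = c(bias - tq * se_bias, bias + tq * se_bias),
                 n_pairs = n, n_subjects = n_subjects),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman: bias %.3f (95%% CI %.3f..%.3f), ",
                     "LoA [%.3f, %.3f], ratio %.3f, n = %d pairs / %d subjects>\n"),
              x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high,
              x$ba_ratio, x$n_pairs, x$n_subjects))
  invisible(x)
}

# Pair estimated window metrics with per-window truth on window index.
pair_with_truth <- function(metrics, truth, metric, truth_col = metric) {
  mm <- merge(metrics, truth, by.x = "window_index", by.y = "index",
              suffixes = c("", ".truth"))
  est_col <- switch(metric, hr = "hr_bpm", sdnn = "sdnn_ms",
                    rmssd = "rmssd_ms", rr = "rr_brpm", metric)
  tru_col <- paste0(est_col, ".truth")
  if (!tru_col %in% names(mm)) tru_col <- est_col
  ok <- is.finite(mm[[est_col]]) & is.finite(mm[[tru_col]])
  data.frame(window = mm$window_index[ok], test = mm[[est_col]][ok],
             ref = mm[[tru_col]][ok])
}

#' Window-duration sensitivity re-analysis
#'
#' Re-segments and fully re-analyzes each session at every window
#' duration (conventionally 60, 45 and 30 s) and tabulates the error of
#' each metric against the session's ground truth. Shorter windows
#' yield more (noisier) measurements; the table makes the accuracy /
#' duration trade-off explicit.
#'
#' @param sessions list of [simulate_session()] results (or any list
#'   with elements `ppg`, `motion`, `truth`).
#' @param durations window durations in seconds.
#' @param metrics metric names among `"hr"`, `"sdnn"`, `"rmssd"`,
#'   `"rr"`.
#' @param ... passed to [compute_window_metrics()].
#' @return Data frame with columns `duration_s`, `metric`, `n`, `mae`,
#'   `mae_sd`, `mape`, `mape_sd`.
#' @export
window_sensitivity <- function(sessions, durations = c(60, 45, 30),
                               metrics = c("hr", "sdnn", "rmssd", "rr"),
                               ...) {
  rows <- list()
  for (d in durations) {
    pooled <- stats::setNames(
      lapply(metrics, function(m) data.frame()), metrics)
    for (s in sessions) {
      wm <- compute_window_metrics(s$ppg, s$motion, window_s = d, ...)
      tr <- window_truth(s$truth$beat_times, s$truth$ibis_ms,
                         s$truth$rr_brpm, duration(s$ppg), window_s = d)
      for (m in metrics) {
        pr <- pair_with_truth(wm, tr, m)
        pooled[[m]] <- rbind(pooled[[m]], pr)
      }
    }
    for (m in metrics) {
      p <- pooled[[m]]
      if (nrow(p) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          duration_s = d, metric = m, n = 0L, mae = NA_real_,
          mae_sd = NA_real_, mape = NA_real_, mape_sd = NA_real_)
      } else {
        em <- error_metrics(p)
        rows[[length(rows) + 1]] <- data.frame(
          duration_s = d, metric = m, n = em$n, mae = em$mae,
          mae_sd = em$mae_sd, mape = em$mape, mape_sd = em$mape_sd)
      }
    }
  }
  do.call(rbind, rows)
}

#' Bilateral (left/right) agreement of window metrics
#'
#' Pairs simultaneously recorded left- and right-site window metrics by
#' window index and reports the mean absolute pairwise difference (and
#' its sample SD) per metric, over windows where both sides are valid.
#'
#' @param left,right `window_metrics` data frames.
#' @param metrics metric column names to compare.
#' @return Data frame with columns `metric`, `n`, `mean_abs_diff`,
#'   `sd_abs_diff`; zero rows when no window is valid on both sides.
#' @export
bilateral_agreement <- function(left, right,
                                metrics = c("hr_bpm", "sdnn_ms",
                                            "rmssd_ms", "rr_brpm")) {
  mm <- merge(left, right, by = "window_index", suffixes = c(".l", ".r"))
  rows <- lapply(metrics, function(m) {
    l <- mm[[paste0(m, ".l")]]
    r <- mm[[paste0(m, ".r")]]
    ok <- is.finite(l) & is.finite(r)
    if (!any(ok)) return(NULL)
    ad <- abs(l[ok] - r[ok])
    data.frame(metric = m, n = sum(ok), mean_abs_diff = mean(ad),
               sd_abs_diff = if (sum(ok) > 1) stats::sd(ad) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metric = character(0), n = integer(0),
                      mean_abs_diff = numeric(0), sd_abs_diff = numeric(0))
  out
}
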