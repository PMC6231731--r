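# CSV / JSON interchange and the offline pipeline entry point. All
# interchange is plain text: waveform CSV (`time_s,value` or
# `time_s,ir,red`), motion CSV (`time_s,ax,ay,az`), per-window metrics
# CSV, and a ground-truth JSON for simulated sessions.

#' Read waveform(s) from CSV
#'
#' Expects a header `time_s,value` (one channel) or `time_s,<label>...`
#' (one waveform per value column). Timestamps must be strictly
#' increasing with a constant step (1 ppm relative tolerance); the
#' first offending row is named in the error. Non-finite sample values
#' are rejected.
#'
#' @param path CSV file path.
#' @return A `ppg_waveform`, or a named list of them for multi-channel
#'   files.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_s" || ncol(df) < 2)
    stop("expected header time_s,<value column(s)>")
  tt <- df$time_s
  if (nrow(df) < 2) stop("need at least 2 samples")
  dt <- diff(tt)
  bad <- which(dt <= 0)
  if (length(bad))  # +2: header line plus 1-based diff offset
    stop(sprintf("non-increasing timestamp at row %d", bad[1] + 2L))
  dt_med <- stats::median(dt)
  off <- which(abs(dt - dt_med) > 1e-6 * dt_med + 1e-9)
  if (length(off))
    stop(sprintf("irregular sampling step at row %d", off[1] + 2L))
  fs <- (nrow(df) - 1) / (tt[nrow(df)] - tt[1])
  chans <- names(df)[-1]
  out <- lapply(chans, function(ch) {
    v <- df[[ch]]
    if (!all(is.finite(v)))
      stop(sprintf("non-finite value in column '%s'", ch))
    waveform(v, fs = fs, t0 = tt[1], label = ch)
  })
  names(out) <- chans
  if (length(out) == 1L) out[[1]] else out
}

#' Write waveform(s) to CSV
#'
#' @param w a `ppg_waveform` or named list of equal-length waveforms
#'   sharing `fs` and `t0`.
#' @param path output path.
#' @export
write_waveform_csv <- function(w, path) {
  ws <- if (inherits(w, "ppg_waveform")) stats::setNames(list(w), w$label) else w
  tt <- sample_times(ws[[1]])
  df <- data.frame(time_s = sprintf("%.9f", tt))
  for (nm in names(ws)) df[[nm]] <- ws[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a 3-axis motion CSV as a magnitude trace
#'
#' Header `time_s,ax,ay,az`; the trace magnitude is the Euclidean norm
#' of the three axes.
#'
#' @param path CSV file path.
#' @return A `ppg_motion`.
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("expected header time_s,ax,ay,az")
  mag <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
  fs <- (nrow(df) - 1) / (df$time_s[nrow(df)] - df$time_s[1])
  motion_trace(mag, fs = fs, t0 = df$time_s[1])
}

#' Write a motion trace to CSV
#'
#' The magnitude is stored on the x axis (`ay = az = 0`), so reading it
#' back reproduces the magnitude exactly.
#'
#' @param m a `ppg_motion`.
#' @param path output path.
#' @export
write_motion_csv <- function(m, path) {
  df <- data.frame(time_s = sprintf("%.9f", sample_times(m)),
                   ax = m$magnitude, ay = 0, az = 0)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Default pipeline configuration
#'
#' Nested configuration for every stage, serializable to JSON with
#' [read_config()] as the inverse. Unknown keys in a configuration file
#' are rejected.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    bandpass = list(lo_hz = 0.3, hi_hz = 10.0),
    window = list(duration_s = 60),
    quality = list(hnr_window_s = 6, hnr_step_s = 1, hnr_threshold_db = 3,
                   motion_threshold = 0.5, lag_search_s = c(1 / 3, 2)),
    beats = list(min_ibi_s = 0.33, max_ibi_s = 2.0, template_corr_min = 0.8,
                 stft_band_hz = c(0.5, 3.0), min_qualified_frac = 0.5),
    vitals = list(min_beats_per_min = 30, rr_band_hz = c(0.1, 0.5),
                  rr_quality_min = 0.5, rr_agree_brpm = 4,
                  mad_threshold = 6.25),
    seed = 1, verbosity = 1
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Values present in the file override the defaults; keys not present
#' in [default_config()] raise an error.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_config()
  merged <- merge_config(base, user, prefix = "")
  class(merged) <- "pipeline_config"
  merged
}

merge_config <- function(base, user, prefix) {
  for (k in names(user)) {
    full <- paste0(prefix, k)
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(full, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

# Materialize stage configuration objects from a pipeline_config.
stage_configs <- function(cfg) {
  list(
    qcfg = quality_config(hnr_window_s = cfg$quality$hnr_window_s,
                          hnr_step_s = cfg$quality$hnr_step_s,
                          hnr_threshold_db = cfg$quality$hnr_threshold_db,
                          motion_threshold = cfg$quality$motion_threshold,
                          lag_search_s = cfg$quality$lag_search_s),
    bcfg = beat_config(min_ibi_s = cfg$beats$min_ibi_s,
                       max_ibi_s = cfg$beats$max_ibi_s,
                       template_corr_min = cfg$beats$template_corr_min,
                       stft_band_hz = cfg$beats$stft_band_hz,
                       min_qualified_frac = cfg$beats$min_qualified_frac,
                       motion_threshold = cfg$quality$motion_threshold),
    vcfg = vitals_config(min_beats_per_min = cfg$vitals$min_beats_per_min,
                         rr_band_hz = cfg$vitals$rr_band_hz,
                         rr_quality_min = cfg$vitals$rr_quality_min,
                         rr_agree_brpm = cfg$vitals$rr_agree_brpm,
                         outlier = outlier_config(cfg$vitals$mad_threshold))
  )
}

#' Write per-window metrics to CSV
#'
#' @param metrics a `window_metrics` data frame.
#' @param path output path.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- as.data.frame(metrics)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "window_index"
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, round(x, 6)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write simulation ground truth to JSON
#'
#' @param truth the `truth` element of a [simulate_session()] result.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
}

#' Run the offline processing pipeline on CSV inputs
#'
#' Offline equivalent of the device's cloud processing: reads a PPG
#' waveform CSV (and optionally a motion CSV), computes per-window
#' metrics, writes them to `out_dir/metrics.csv`, and logs per-window
#' qualification decisions and counts. Deterministic given the inputs
#' and configuration.
#'
#' @param input path to the waveform CSV (first value column is used
#'   when several are present).
#' @param motion_path optional motion CSV path; when missing the
#'   pipeline runs with motion gating disabled and logs a warning.
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @return The `window_metrics` data frame, invisibly.
#' @export
run_pipeline <- function(input, motion_path = NULL,
                         config = default_config(), out_dir = NULL) {
  w <- read_waveform_csv(input)
  if (is.list(w) && !inherits(w, "ppg_waveform")) w <- w[[1]]
  m <- NULL
  if (!is.null(motion_path)) {
    if (file.exists(motion_path)) {
      m <- read_motion_csv(motion_path)
    } else {
      warning("motion file not found; motion gating disabled")
    }
  }
  sc <- stage_configs(config)
  metrics <- compute_window_metrics(
    w, m, window_s = config$window$duration_s,
    qcfg = sc$qcfg, bcfg = sc$bcfg, vcfg = sc$vcfg,
    lo = config$bandpass$lo_hz, hi = config$bandpass$hi_hz)
  if (config$verbosity >= 1) {
    for (i in seq_len(nrow(metrics))) {
      r <- metrics[i, ]
      message(sprintf(
        "window %d @ %gs: hnr %.2f dB, qualified=%s, beats=%d, outliers=%d",
        r$window_index, r$window_start_s, r$hnr_db, r$qualified, r$n_beats,
        r$n_outliers_removed))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
  }
  invisible(metrics)
}
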