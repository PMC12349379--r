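#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 2-8 mm
#' validity range, dilation-speed MAD multiplier 20, moving-average window
#' 23 samples with multiplier 18, upsampling to 1000 Hz, 250 ms maximum
#' bridgeable gap, 400 ms minimum baseline window, and 33 ms downsampling
#' bins for a 30 Hz facial stream.
#'
#' @param column_map see [default_column_map()].
#' @param trim_start_ms,trim_end_ms optional procedure window (from video
#'   annotation of task start/end); `NULL` keeps the whole recording.
#' @param min_mm,max_mm diameter validity bounds.
#' @param n_mad dilation-speed threshold multiplier.
#' @param ma_window,n_ma moving-average window (samples) and multiplier.
#' @param ma_align moving-average alignment (`"trailing"` or `"centered"`).
#' @param iterate_outliers iterate both outlier detectors to convergence?
#' @param target_rate_hz upsampling rate.
#' @param max_gap_ms longest original gap interpolation may bridge.
#' @param method interpolation method.
#' @param baseline_min_ms minimum baseline window span.
#' @param baseline_max_gap_ms consecutiveness tolerance in the baseline scan.
#' @param bin_width_ms downsampling bin width.
#' @param output_rate_hz nominal downsampled rate.
#' @param verbose print per-stage progress?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(column_map = default_column_map(),
                            trim_start_ms = NULL, trim_end_ms = NULL,
                            min_mm = 2, max_mm = 8,
                            n_mad = 20,
                            ma_window = 23, n_ma = 18,
                            ma_align = "trailing",
                            iterate_outliers = FALSE,
                            target_rate_hz = 1000,
                            max_gap_ms = 250,
                            method = "pchip",
                            baseline_min_ms = 400,
                            baseline_max_gap_ms = 12.5,
                            bin_width_ms = 33,
                            output_rate_hz = 30,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Restrict a multimodal table to the procedure window
#'
#' Keeps rows with `start_ms <= timestamp <= end_ms`.  The window comes
#' from video annotation of the procedure (task start and end events) and
#' is supplied as plain timestamps.
#'
#' @param table a `multimodal_table`.
#' @param start_ms,end_ms window bounds in ms, `start_ms < end_ms`.
#' @return The trimmed table.
#' @export
trim_to_procedure <- function(table, start_ms, end_ms) {
  stopifnot(start_ms < end_ms)
  cmap <- attr(table, "column_map")
  ts <- table[[cmap$timestamp]]
  keep <- ts >= start_ms & ts <= end_ms
  if (!any(keep)) warning("trim window contains no rows", call. = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, column_map = cmap,
            class = c("multimodal_table", "data.frame"))
}

# Run `expr`, rethrowing any error with the stage name attached so a
# failing pipeline reports where it died.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full preprocessing pipeline
#'
#' Executes, in order: procedure trimming, per-modality splitting,
#' per-eye null/duplicate removal, range filtering, dilation-speed (MAD)
#' outlier removal, moving-average local outlier removal, PCHIP upsampling
#' to the millisecond grid with long-gap masking, binocular alignment by
#' outer join, cross-eye regression imputation, mean pupil computation,
#' baseline detection and normalization, bin-average downsampling, and the
#' full outer join with the facial stream.
#'
#' @param table a `multimodal_table` (from [read_multimodal()] or
#'   [generate_recording()]), or a path to a CSV.
#' @param config a [pipeline_config()].
#' @return A list of class `pupil_pipeline` with elements `merged` (the
#'   integrated 30 Hz table), `binocular` (the processed millisecond-grid
#'   table with a `normalized` column), `baseline`
#'   (a `baseline_result`), `model` (the `cross_eye_model`), and `report`
#'   (per-stage sample counts).
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  if (is.character(table)) {
    table <- read_multimodal(table, column_map = config$column_map)
  }
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  report <- list()
  note <- function(stage, eye, n) {
    report[[length(report) + 1]] <<- data.frame(
      stage = stage, eye = eye, n_samples = n, stringsAsFactors = FALSE)
  }

  if (!is.null(config$trim_start_ms) && !is.null(config$trim_end_ms)) {
    table <- with_stage("trim", trim_to_procedure(
      table, config$trim_start_ms, config$trim_end_ms))
  }
  note("input", "both", nrow(table))

  streams <- with_stage("split", split_streams(table))
  if (nrow(streams$left) == 0 && nrow(streams$right) == 0) {
    stop("pipeline stage 'split' failed: no pupil samples in input",
         call. = FALSE)
  }

  clean_one <- function(trace, eye) {
    note("split", eye, nrow(trace))
    trace <- with_stage("drop_null_duplicates", drop_null_and_duplicates(trace))
    note("null/duplicate removal", eye, nrow(trace))
    trace <- with_stage("range_filter",
                        filter_range(trace, config$min_mm, config$max_mm))
    note("range filter", eye, nrow(trace))
    trace <- with_stage("mad_outliers", remove_speed_outliers(
      trace, n_mad = config$n_mad, iterate = config$iterate_outliers))
    note("dilation-speed outliers", eye, nrow(trace))
    trace <- with_stage("ma_outliers", remove_local_outliers(
      trace, window_k = config$ma_window, n_ma = config$n_ma,
      align = config$ma_align, iterate = config$iterate_outliers,
      warn_window = FALSE))
    note("moving-average outliers", eye, nrow(trace))
    trace
  }
  left <- clean_one(streams$left, "left")
  right <- clean_one(streams$right, "right")
  say("cleaned: left %d, right %d samples", nrow(left), nrow(right))

  # baseline window is located on the raw (pre-interpolation) binocular data
  raw_binoc <- with_stage("baseline_scan", align_eyes(
    round_timestamps(left, 1), round_timestamps(right, 1)))
  window <- with_stage("baseline_scan", find_baseline_window(
    raw_binoc, config$baseline_min_ms, config$baseline_max_gap_ms))

  up_one <- function(trace, eye) {
    up <- with_stage("upsample", upsample(
      trace, target_rate = config$target_rate_hz, method = config$method))
    up <- with_stage("gap_mask", mask_long_gaps(up, trace, config$max_gap_ms))
    note("upsampled+masked", eye, nrow(up))
    up
  }
  left_up <- up_one(left, "left")
  right_up <- up_one(right, "right")

  binoc <- with_stage("align", align_eyes(left_up, right_up))
  model <- with_stage("cross_eye_fit", fit_cross_eye(binoc))
  binoc <- with_stage("impute", impute_missing_eye(binoc, model))
  binoc <- with_stage("mean_pupil", mean_pupil(binoc))
  note("binocular grid", "both", nrow(binoc))

  baseline <- with_stage("baseline", compute_baseline(binoc, window))
  binoc$normalized <- with_stage("normalize", normalize_dilation(
    binoc$mean, baseline$baseline_mm))
  say("baseline %.3f mm over [%.0f, %.0f] ms", baseline$baseline_mm,
      window[1], window[2])

  binned <- with_stage("downsample", downsample_bins(
    binoc, bin_width_ms = config$bin_width_ms,
    output_rate = config$output_rate_hz))
  note("binned pupil", "both", nrow(binned))

  facial <- with_stage("facial", round_timestamps(streams$facial, 1))
  note("facial", "both", nrow(facial))
  merged <- with_stage("merge", merge_full_outer(binned, facial))
  note("merged", "both", nrow(merged))

  structure(list(
    merged = merged,
    binocular = binoc,
    baseline = baseline,
    model = model,
    mean_normalized_dilation = mean_normalized_dilation(binoc$normalized),
    report = do.call(rbind, report),
    config = config
  ), class = "pupil_pipeline")
}

#' @export
print.pupil_pipeline <- function(x, ...) {
  cat("Pupillometry preprocessing pipeline result\n")
  cat(sprintf("  baseline: %.4f mm over [%.0f, %.0f] ms\n",
              x$baseline$baseline_mm, x$baseline$window[1],
              x$baseline$window[2]))
  cat(sprintf("  mean normalized dilation: %.4f\n",
              x$mean_normalized_dilation))
  cat(sprintf("  cross-eye fit: right = %.3f*left + %.3f (r^2 = %.3f, n = %d)\n",
              x$model$slope_lr, x$model$intercept_lr, x$model$r_squared,
              x$model$n_fit))
  cat(sprintf("  merged output: %d rows at %.0f Hz nominal\n",
              nrow(x$merged), x$config$output_rate_hz))
  cat("  stage sample counts:\n")
  rep <- x$report
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("    %-28s %-5s %8d\n", rep$stage[i], rep$eye[i],
                rep$n_samples[i]))
  }
  invisible(x)
}
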