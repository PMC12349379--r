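#' Find the baseline window
#'
#' Scans the *raw* (cleaned, pre-interpolation) binocular data from the
#' first timestamp for the earliest stretch in which both eyes are valid at
#' every sample and successive samples are consecutive, lasting at least
#' `min_duration_ms`.  "Consecutive" is operationalized as an inter-sample
#' gap of at most `max_gap_ms`; the default 12.5 ms is 1.5 times the
#' nominal 120 Hz frame period, tolerating timestamp jitter but not a
#' dropped frame run.  The full extent of the first qualifying stretch is
#' returned.
#'
#' @param raw_table a `binocular_table` built from the cleaned,
#'   pre-interpolation traces.
#' @param min_duration_ms minimum window span (default 400 ms).
#' @param max_gap_ms maximum inter-sample gap within the window
#'   (default 12.5 ms).
#' @return Numeric `c(t_start, t_end)` in ms.
#' @export
find_baseline_window <- function(raw_table, min_duration_ms = 400,
                                 max_gap_ms = 12.5) {
  stopifnot(min_duration_ms > 0, max_gap_ms > 0)
  valid <- !is.na(raw_table$left) & !is.na(raw_table$right)
  t_valid <- raw_table$timestamp[valid]
  if (length(t_valid) > 0) {
    # split the valid timestamps into runs of consecutive samples
    brk <- c(0, which(diff(t_valid) > max_gap_ms), length(t_valid))
    for (j in seq_len(length(brk) - 1)) {
      run <- t_valid[(brk[j] + 1):brk[j + 1]]
      if (run[length(run)] - run[1] >= min_duration_ms) {
        return(c(run[1], run[length(run)]))
      }
    }
  }
  stop("no valid baseline period (no consecutive binocular stretch of ",
       min_duration_ms, " ms)")
}

#' Compute the baseline pupil diameter
#'
#' Averages the *processed* mean-pupil series over the baseline window.
#' The window is located on raw data (so gaps and artifacts cannot be
#' papered over by interpolation when deciding where the baseline is), but
#' the baseline value itself is taken from the refined series.
#'
#' @param processed a `binocular_table` whose `mean` column is filled.
#' @param window numeric `c(t_start, t_end)` from [find_baseline_window()].
#' @return A list of class `baseline_result` with elements `window` and
#'   `baseline_mm`.
#' @export
compute_baseline <- function(processed, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  in_win <- processed$timestamp >= window[1] &
    processed$timestamp <= window[2] & !is.na(processed$mean)
  if (!any(in_win)) stop("compute_baseline: no processed samples in window")
  structure(list(window = window,
                 baseline_mm = mean(processed$mean[in_win])),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("Baseline: %.4f mm over [%.0f, %.0f] ms (%.0f ms window)\n",
              x$baseline_mm, x$window[1], x$window[2],
              diff(x$window)))
  invisible(x)
}

#' Baseline-relative normalized pupil dilation
#'
#' Maps each diameter to its fractional change from baseline,
#' `(d - baseline) / baseline` (dimensionless): 0 at baseline, positive
#' when dilated, negative when constricted.  Missing values stay missing.
#'
#' @param values numeric vector of diameters (mm).
#' @param baseline_mm positive baseline diameter (mm).
#' @return Numeric vector of normalized dilations.
#' @export
normalize_dilation <- function(values, baseline_mm) {
  if (!is.numeric(baseline_mm) || length(baseline_mm) != 1 ||
      is.na(baseline_mm) || baseline_mm <= 0) {
    stop("normalize_dilation: baseline must be a positive scalar")
  }
  (values - baseline_mm) / baseline_mm
}

#' Mean normalized dilation
#'
#' Arithmetic mean of the normalized series over non-missing values: a
#' single summary of how dilated the pupil was, relative to baseline,
#' across the recording.
#'
#' @param normalized numeric vector from [normalize_dilation()].
#' @return Scalar mean.
#' @export
mean_normalized_dilation <- function(normalized) {
  ok <- !is.na(normalized)
  if (!any(ok)) stop("mean_normalized_dilation: all values missing")
  mean(normalized[ok])
}
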