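#' Normalized dilation speed
#'
#' For each sample the dilation speed is the larger of the backward and
#' forward absolute difference quotients,
#' d'_i = max(|d_i - d_{i-1}| / (t_i - t_{i-1}), |d_{i+1} - d_i| / (t_{i+1} - t_i)),
#' in mm/ms.  Dividing by the actual time step normalizes for irregular
#' sampling, so a diameter jump across a long gap is not mistaken for a fast
#' change.  The first and last samples have a single neighbour and use the
#' one-sided quotient; dropping them instead would lose valid data.
#'
#' @param trace an `eye_trace` with strictly increasing timestamps and at
#'   least 2 samples.
#' @return Numeric vector of speeds (mm/ms), same length as the trace.
#' @export
dilation_speed <- function(trace) {
  n <- nrow(trace)
  if (n < 2) stop("insufficient samples for speed metric (need >= 2)")
  dt <- diff(trace$time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  q <- abs(diff(trace$diameter)) / dt
  # q[i] is the quotient between samples i and i+1
  pmax(c(q[1], q), c(q, q[n - 1]))
}

#' Median absolute deviation (raw, no consistency constant)
#'
#' `median(|x - median(x)|)`.  Deliberately *not* scaled by the 1.4826
#' normal-consistency factor that [stats::mad()] applies: the outlier
#' thresholds downstream are defined on the raw MAD, with the scale folded
#' into the multiplier `n`.
#'
#' @param x non-empty numeric vector.
#' @return The raw MAD.
#' @export
mad_raw <- function(x) {
  if (length(x) == 0) stop("mad_raw: empty input")
  stats::median(abs(x - stats::median(x)))
}

#' Dilation-speed outlier threshold
#'
#' `median(d') + n_mad * MAD(d')`.  The multiplier controls sensitivity;
#' the default 20 targets gross artifacts (blink edges, tracking losses)
#' while leaving task-evoked dilation untouched.
#'
#' @param speed numeric vector of dilation speeds (see [dilation_speed()]).
#' @param n_mad positive scaling factor (default 20).
#' @return The scalar threshold in mm/ms.
#' @export
speed_threshold <- function(speed, n_mad = 20) {
  stopifnot(n_mad > 0)
  stats::median(speed) + n_mad * mad_raw(speed)
}

#' Remove global (dilation-speed) outliers
#'
#' Removes exactly the samples whose dilation speed strictly exceeds the
#' MAD-based threshold.  This targets *global* outliers: changes far too
#' fast to be pupil physiology anywhere in the recording.  A single pass is
#' applied by default; `iterate = TRUE` reapplies the detector until no
#' sample is removed (the threshold is recomputed each round).
#'
#' @param trace an `eye_trace` with >= 2 samples.
#' @param n_mad threshold multiplier (default 20).
#' @param iterate reapply until convergence? (default `FALSE`, single pass).
#' @return The surviving `eye_trace`, with attributes `n_removed` and
#'   `removed_time` (timestamps of removed samples).
#' @export
remove_speed_outliers <- function(trace, n_mad = 20, iterate = FALSE) {
  removed_time <- numeric(0)
  repeat {
    sp <- dilation_speed(trace)
    thr <- speed_threshold(sp, n_mad)
    out <- sp > thr
    if (!any(out)) break
    removed_time <- c(removed_time, trace$time[out])
    trace <- rebuild_trace(trace, which(!out))
    if (!iterate || nrow(trace) < 2) break
  }
  attr(trace, "n_removed") <- length(removed_time)
  attr(trace, "removed_time") <- removed_time
  trace
}

#' Moving average with shrinking warm-up window
#'
#' Trailing moving average MA_i = mean(x_{i-k+1}, ..., x_i).  For the first
#' k-1 positions, where a full window is unavailable, the mean of all points
#' up to i is used so the output has full length.  `align = "centered"`
#' switches to a centred window of the same nominal size (shrinking at both
#' edges), an alternative reading of a "local trend".
#'
#' @param x numeric vector.
#' @param window_k window size in samples (>= 1).
#' @param align `"trailing"` (default) or `"centered"`.
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window_k, align = c("trailing", "centered")) {
  align <- match.arg(align)
  stopifnot(window_k >= 1)
  n <- length(x)
  if (n == 0) return(numeric(0))
  k <- as.integer(window_k)
  cs <- cumsum(x)
  if (align == "trailing") {
    lo <- pmax(seq_len(n) - k + 1L, 1L)
  } else {
    h_before <- (k - 1L) %/% 2L
    h_after <- k - 1L - h_before
    lo <- pmax(seq_len(n) - h_before, 1L)
    hi <- pmin(seq_len(n) + h_after, n)
  }
  if (align == "trailing") hi <- seq_len(n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Remove local (moving-average deviation) outliers
#'
#' The global detector compares every sample to the recording-wide median
#' and misses brief excursions that are only anomalous relative to their
#' neighbourhood (partial eyelid occlusions).  This pass computes the
#' absolute deviation of each diameter from its moving-average trend,
#' delta_i = |x_i - MA_i|, and removes samples with
#' delta_i > n_ma * median(delta).  The moving average is computed once on
#' the input trace and not recomputed during removal.
#'
#' The window should span roughly a blink (150-400 ms); at 120 Hz that is
#' 18-48 samples, and the default is 23.  A warning is issued when
#' `window_k` times the trace's median frame period falls outside that
#' span.
#'
#' @param trace a non-empty `eye_trace`.
#' @param window_k moving-average window in samples (default 23).
#' @param n_ma threshold multiplier (default 18).
#' @param align moving-average alignment, see [moving_average()].
#' @param iterate reapply until convergence? (default `FALSE`).
#' @param warn_window warn when the window duration is outside the typical
#'   blink span? (default `TRUE`).
#' @return The surviving `eye_trace`, with attributes `n_removed` and
#'   `removed_time`.
#' @export
remove_local_outliers <- function(trace, window_k = 23, n_ma = 18,
                                  align = "trailing", iterate = FALSE,
                                  warn_window = TRUE) {
  stopifnot(window_k >= 1, n_ma > 0)
  if (nrow(trace) == 0) stop("remove_local_outliers: empty trace")
  if (warn_window && nrow(trace) > 1) {
    period <- stats::median(diff(trace$time))
    span <- window_k * period
    if (span < 150 || span > 400) {
      warning(sprintf(
        "moving-average window spans %.0f ms; outside the typical blink duration of 150-400 ms",
        span), call. = FALSE)
    }
  }
  removed_time <- numeric(0)
  repeat {
    ma <- moving_average(trace$diameter, window_k, align = align)
    dev <- abs(trace$diameter - ma)
    thr <- n_ma * stats::median(dev)
    out <- dev > thr
    if (!any(out)) break
    removed_time <- c(removed_time, trace$time[out])
    trace <- rebuild_trace(trace, which(!out))
    if (!iterate || nrow(trace) == 0) break
  }
  attr(trace, "n_removed") <- length(removed_time)
  attr(trace, "removed_time") <- removed_time
  trace
}
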