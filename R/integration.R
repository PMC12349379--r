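#' Downsample the millisecond pupil table by bin averaging
#'
#' Divides the pupil time base into half-open bins `[k*w, (k+1)*w)` of
#' width `bin_width_ms`, anchored at the first pupil timestamp, and emits
#' one row per non-empty bin: the bin start time and the mean of each
#' pupil column over the samples falling in the bin.  With a 1000 Hz input
#' and the default 33 ms bins, a full bin averages 33 samples, matching a
#' 30 Hz facial stream closely enough for integration.  A 33 ms bin drifts
#' slowly against an exact 30 Hz grid; pass `bin_width_ms = 1000/30` for
#' drift-free binning if preferred.
#'
#' @param table a `binocular_table` (optionally with a `normalized`
#'   column) on the millisecond grid.
#' @param bin_width_ms bin width in ms (default 33).
#' @param output_rate nominal output rate in Hz (default 30); used only to
#'   warn when `bin_width_ms` is inconsistent with it.
#' @return A data frame with `timestamp` (bin start), the averaged numeric
#'   pupil columns, and `n_samples` per bin.
#' @export
downsample_bins <- function(table, bin_width_ms = 33, output_rate = 30) {
  stopifnot(bin_width_ms > 0)
  if (abs(bin_width_ms - 1000 / output_rate) > 1) {
    warning(sprintf("bin width %.2f ms is inconsistent with %.0f Hz (%.2f ms)",
                    bin_width_ms, output_rate, 1000 / output_rate),
            call. = FALSE)
  }
  if (nrow(table) == 0) stop("downsample_bins: empty table")
  anchor <- table$timestamp[1]
  bin <- floor((table$timestamp - anchor) / bin_width_ms)
  cols <- intersect(c("left", "right", "mean", "normalized"), names(table))
  ubin <- sort(unique(bin))
  idx <- match(bin, ubin)
  out <- data.frame(timestamp = anchor + ubin * bin_width_ms)
  for (cl in cols) {
    sums <- tapply(table[[cl]], idx, function(v) mean(v, na.rm = TRUE))
    v <- as.numeric(sums)
    v[is.nan(v)] <- NA
    out[[cl]] <- v
  }
  out$n_samples <- as.integer(tabulate(idx, nbins = length(ubin)))
  out
}

#' Merge binned pupil data with the facial stream by full outer join
#'
#' Joins on exact (rounded) millisecond timestamps, keeping every row from
#' both inputs; the side without a match carries missing values.  Facial
#' metrics are never interpolated onto the pupil grid: muscle-based
#' expression metrics have no meaningful between-frame values, so the
#' union time base with explicit missingness is the honest representation.
#'
#' @param pupil the binned pupil table from [downsample_bins()].
#' @param facial a `facial_table` with rounded timestamps.
#' @return A data frame of class `merged_table`, sorted by timestamp, with
#'   logical `has_pupil` / `has_facial` modality flags.
#' @export
merge_full_outer <- function(pupil, facial) {
  p <- as.data.frame(pupil)
  f <- as.data.frame(facial)
  p$has_pupil <- TRUE
  if (nrow(f) > 0) f$has_facial <- TRUE
  m <- merge(p, f, by = "timestamp", all = TRUE, sort = TRUE)
  if (!"has_facial" %in% names(m)) m$has_facial <- NA
  m$has_pupil <- !is.na(m$has_pupil)
  m$has_facial <- !is.na(m$has_facial)
  rownames(m) <- NULL
  structure(m, class = c("merged_table", "data.frame"))
}

#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("<merged_table: %d rows (%d pupil, %d facial, %d both)>\n",
              nrow(x), sum(x$has_pupil), sum(x$has_facial),
              sum(x$has_pupil & x$has_facial)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
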