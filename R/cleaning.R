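#' Remove null samples and duplicate timestamps
#'
#' Drops samples with a missing diameter and, among samples sharing an exact
#' raw timestamp (a known export software error), keeps the first
#' occurrence.  Relative order is otherwise preserved; output timestamps are
#' strictly increasing.
#'
#' @param trace an `eye_trace`.
#' @return A cleaned `eye_trace` with attributes `n_null` and `n_duplicate`
#'   recording how many samples each rule removed.
#' @export
drop_null_and_duplicates <- function(trace) {
  keep_null <- !is.na(trace$diameter)
  n_null <- sum(!keep_null)
  t_sub <- trace$time[keep_null]
  keep_dup <- !duplicated(t_sub)
  out <- rebuild_trace(trace, which(keep_null)[keep_dup])
  attr(out, "n_null") <- n_null
  attr(out, "n_duplicate") <- sum(!keep_dup)
  out
}

#' Filter physiologically invalid pupil diameters
#'
#' Retains only samples whose diameter lies inside the physiologically
#' plausible range (inclusive bounds): values outside it arise from blinks,
#' tracker detection errors or head movement, not from the pupil.  The
#' default 2-8 mm range suits adult participants; the bounds are parameters
#' because populations differ.
#'
#' @param trace an `eye_trace` with no missing diameters.
#' @param min_mm,max_mm inclusive validity bounds in millimetres
#'   (defaults 2 and 8).
#' @return A filtered `eye_trace` with attribute `n_removed`.
#' @export
filter_range <- function(trace, min_mm = 2, max_mm = 8) {
  stopifnot(is.numeric(min_mm), is.numeric(max_mm),
            min_mm > 0, min_mm < max_mm)
  keep <- !is.na(trace$diameter) &
    trace$diameter >= min_mm & trace$diameter <= max_mm
  out <- rebuild_trace(trace, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}
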