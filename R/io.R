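#' Default column mapping for multimodal exports
#'
#' Column names vary between eye-tracking exports; the pipeline resolves the
#' timestamp and per-eye pupil columns through a mapping.  The defaults match
#' an iMotions 10 wide export.  Every column not named here is treated as a
#' facial-expression metric.
#'
#' @param timestamp,left,right column names in the CSV header.
#' @return A named list with entries `timestamp`, `left`, `right`.
#' @export
default_column_map <- function(timestamp = "Timestamp",
                               left = "ET_PupilLeft",
                               right = "ET_PupilRight") {
  list(timestamp = timestamp, left = left, right = right)
}

#' Sentinel strings treated as missing values
#'
#' iMotions-style exports mark absent samples with several sentinels
#' (empty cell, `"Nan"`, `"-1"`); the set is configurable because the
#' convention is not standardized across export versions.
#'
#' @return Character vector of missing-value markers.
#' @export
default_na_strings <- function() c("", "NA", "NaN", "Nan", "nan", "-1")

#' Read a multimodal wide-table CSV
#'
#' Reads a wide export holding one timestamp column plus pupil diameter
#' columns (nominally 120 Hz) and facial-expression metric columns
#' (nominally 30 Hz), where any row may carry only one modality.  All cells
#' are parsed as numeric; sentinel strings become `NA`, unparseable cells
#' raise a warning and become `NA`, and rows are sorted ascending by
#' timestamp.  No rows are dropped.
#'
#' @param path path to a CSV file (RFC 4180, header row required).
#' @param column_map see [default_column_map()].
#' @param na_strings sentinel strings mapped to missing.
#' @return A data frame of class `multimodal_table`, sorted by timestamp,
#'   with the column map stored as an attribute.
#' @export
read_multimodal <- function(path, column_map = default_column_map(),
                            na_strings = default_na_strings()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!column_map$timestamp %in% names(raw)) {
    stop("timestamp column '", column_map$timestamp,
         "' not found in ", path, " (configuration error)")
  }
  parsed <- raw
  for (col in names(raw)) {
    x <- raw[[col]]
    x[x %in% na_strings] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad)) {
      warning(sprintf("column '%s': %d unparseable cell(s) set to missing",
                      col, sum(bad)), call. = FALSE)
    }
    parsed[[col]] <- num
  }
  ts <- parsed[[column_map$timestamp]]
  if (anyNA(ts)) stop("timestamp column contains missing values")
  if (any(ts < 0)) stop("timestamps must be non-negative")
  parsed <- parsed[order(ts), , drop = FALSE]
  rownames(parsed) <- NULL
  structure(parsed,
            column_map = column_map,
            class = c("multimodal_table", "data.frame"))
}

#' Write a multimodal table (or any pipeline table) as CSV
#'
#' All writers in the package emit the same dialect (comma-separated, header
#' row, `"Nan"` for missing) so stages can be chained through files on disk.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodal <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   na = "Nan", quote = FALSE)
  invisible(path)
}

#' Split a multimodal table into per-modality streams
#'
#' Extracts the left and right pupil traces and the facial metric table.
#' Each eye keeps only rows where that eye's diameter is present; the facial
#' table keeps rows with at least one metric present.  Each eye is processed
#' independently downstream, so no cross-eye row matching happens here.
#'
#' @param table a `multimodal_table` from [read_multimodal()].
#' @return A list with elements `left`, `right` (class `eye_trace`) and
#'   `facial` (class `facial_table`).
#' @export
split_streams <- function(table) {
  cmap <- attr(table, "column_map")
  if (is.null(cmap)) cmap <- default_column_map()
  ts <- table[[cmap$timestamp]]
  one_eye <- function(col, eye) {
    if (is.null(col) || !col %in% names(table)) {
      return(eye_trace(numeric(0), numeric(0), eye = eye))
    }
    keep <- !is.na(table[[col]])
    eye_trace(ts[keep], table[[col]][keep], eye = eye)
  }
  left <- one_eye(cmap$left, "left")
  right <- one_eye(cmap$right, "right")
  facial_cols <- setdiff(names(table),
                         unlist(cmap[c("timestamp", "left", "right")]))
  if (length(facial_cols) == 0) {
    facial <- facial_table(numeric(0),
                           as.data.frame(matrix(numeric(0), nrow = 0, ncol = 0)))
  } else {
    metr <- table[, facial_cols, drop = FALSE]
    keep <- rowSums(!is.na(metr)) > 0
    facial <- facial_table(ts[keep], metr[keep, , drop = FALSE])
  }
  list(left = left, right = right, facial = facial)
}

# Half-away-from-zero rounding to the nearest multiple of `precision`.
# (base round() rounds half to even, which would split ties unpredictably
# between export software conventions.)
round_half_away <- function(x, precision = 1) {
  sign(x) * floor(abs(x) / precision + 0.5) * precision
}

#' Round timestamps to a fixed precision
#'
#' Rounds every timestamp half-away-from-zero to the nearest multiple of
#' `precision` (milliseconds).  If rounding makes two samples share a
#' timestamp, their values are averaged rather than dropped, so no valid
#' data is discarded.
#'
#' @param x an `eye_trace` or `facial_table`.
#' @param precision rounding step in milliseconds (default 1 ms).
#' @return An object of the same class with rounded, strictly increasing
#'   timestamps.
#' @export
round_timestamps <- function(x, precision = 1) {
  stopifnot(precision > 0)
  UseMethod("round_timestamps")
}

#' @export
round_timestamps.eye_trace <- function(x, precision = 1) {
  if (nrow(x) == 0) return(x)
  t_new <- round_half_away(x$time, precision)
  if (anyDuplicated(t_new)) {
    d <- tapply(x$diameter, t_new, mean)
    prov <- tapply(x$provenance, t_new, function(p) p[[1]])
    tt <- as.numeric(names(d))
    o <- order(tt)
    eye_trace(tt[o], as.numeric(d)[o], eye = attr(x, "eye"),
              provenance = as.character(prov)[o])
  } else {
    eye_trace(t_new, x$diameter, eye = attr(x, "eye"),
              provenance = x$provenance)
  }
}

#' @export
round_timestamps.facial_table <- function(x, precision = 1) {
  if (nrow(x) == 0) return(x)
  t_new <- round_half_away(x$timestamp, precision)
  if (anyDuplicated(t_new)) {
    agg <- stats::aggregate(x[, -1, drop = FALSE], by = list(timestamp = t_new),
                            FUN = function(v) mean(v, na.rm = TRUE))
    for (j in seq_along(agg)) agg[[j]][is.nan(agg[[j]])] <- NA
    agg <- agg[order(agg$timestamp), , drop = FALSE]
    facial_table(agg$timestamp, agg[, -1, drop = FALSE])
  } else {
    facial_table(t_new, x[, -1, drop = FALSE])
  }
}
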