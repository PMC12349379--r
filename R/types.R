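#' Construct a single-eye pupil trace
#'
#' An `eye_trace` is the package's container for one eye's pupil diameter
#' time series: a data frame with columns `time` (milliseconds), `diameter`
#' (millimetres) and `provenance` (one of `"observed"`, `"interpolated"`,
#' `"imputed"`), plus an `eye` attribute.
#'
#' @param time numeric vector of timestamps in milliseconds.
#' @param diameter numeric vector of pupil diameters in millimetres
#'   (`NA` for missing samples).
#' @param eye `"left"` or `"right"`.
#' @param provenance character vector recycled to the trace length.
#' @return A data frame of class `eye_trace`.
#' @export
eye_trace <- function(time, diameter, eye = c("left", "right"),
                      provenance = "observed") {
  eye <- match.arg(eye)
  stopifnot(length(time) == length(diameter), is.numeric(time))
  if (anyNA(time)) stop("timestamps must not be missing")
  if (any(time < 0)) stop("timestamps must be non-negative")
  out <- data.frame(
    time = as.numeric(time),
    diameter = as.numeric(diameter),
    provenance = rep_len(as.character(provenance), length(time)),
    stringsAsFactors = FALSE
  )
  structure(out, eye = eye, class = c("eye_trace", "data.frame"))
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace: %s eye, %d samples", attr(x, "eye"), nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %.0f-%.0f ms", min(x$time), max(x$time)))
  }
  cat(">\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# Rebuild an eye_trace after row subsetting, keeping attributes.
rebuild_trace <- function(template, rows) {
  eye_trace(template$time[rows], template$diameter[rows],
            eye = attr(template, "eye"),
            provenance = template$provenance[rows])
}

#' Construct a facial-expression metric table
#'
#' @param timestamp numeric vector of timestamps in milliseconds.
#' @param metrics data frame (or named list) of numeric metric columns.
#' @return A data frame of class `facial_table` with a `timestamp` column
#'   followed by one column per metric.
#' @export
facial_table <- function(timestamp, metrics) {
  metrics <- as.data.frame(metrics, stringsAsFactors = FALSE)
  stopifnot(nrow(metrics) == length(timestamp))
  out <- cbind(data.frame(timestamp = as.numeric(timestamp)), metrics)
  structure(out, class = c("facial_table", "data.frame"))
}

#' @export
print.facial_table <- function(x, ...) {
  cat(sprintf("<facial_table: %d rows, %d metrics>\n",
              nrow(x), ncol(x) - 1L))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# Internal constructor for the binocular (left/right/mean) table.
new_binocular_table <- function(df) {
  needed <- c("timestamp", "left", "right", "mean",
              "left_provenance", "right_provenance")
  stopifnot(all(needed %in% names(df)))
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("binocular_table", "data.frame"))
}

#' @export
print.binocular_table <- function(x, ...) {
  both <- sum(!is.na(x$left) & !is.na(x$right))
  cat(sprintf("<binocular_table: %d rows (%d with both eyes)>\n",
              nrow(x), both))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
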