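#' Align left and right eye traces by outer join
#'
#' Joins the two (millisecond-grid) traces on exact timestamps, keeping the
#' union of both time bases: where one eye has no sample at a timestamp the
#' other observed, that side is missing.  No samples are dropped.
#'
#' @param left,right `eye_trace` objects, timestamps on a common grid
#'   (round with [round_timestamps()] first if needed).
#' @return A `binocular_table` with columns `timestamp`, `left`, `right`,
#'   `mean` (all `NA` until [mean_pupil()]), and per-eye provenance.
#' @export
align_eyes <- function(left, right) {
  if (nrow(left) == 0 && nrow(right) == 0) {
    stop("align_eyes: both traces are empty")
  }
  lf <- data.frame(timestamp = left$time, left = left$diameter,
                   left_provenance = left$provenance,
                   stringsAsFactors = FALSE)
  rt <- data.frame(timestamp = right$time, right = right$diameter,
                   right_provenance = right$provenance,
                   stringsAsFactors = FALSE)
  m <- merge(lf, rt, by = "timestamp", all = TRUE, sort = TRUE)
  m$mean <- NA_real_
  new_binocular_table(m[, c("timestamp", "left", "right", "mean",
                            "left_provenance", "right_provenance")])
}

#' Fit the cross-eye linear regression
#'
#' Ordinary least squares in both directions (right from left, and left
#' from right) on rows where both eyes are present.  Two directional fits
#' are kept, rather than one symmetric fit, because the prediction
#' direction depends on which eye is missing at a given timestamp.  The
#' model is per recording: anisocoria (a stable left/right size offset) is
#' individual, so coefficients must not be pooled across participants.
#'
#' @param table a `binocular_table`.
#' @param min_overlap warn when fewer co-observed rows than this support
#'   the fit (default 30).
#' @return An object of class `cross_eye_model` with elements `slope_lr`,
#'   `intercept_lr`, `slope_rl`, `intercept_rl`, `n_fit`, `r_squared`.
#' @export
fit_cross_eye <- function(table, min_overlap = 30) {
  both <- !is.na(table$left) & !is.na(table$right)
  n_fit <- sum(both)
  if (n_fit < 2) stop("insufficient binocular overlap (need >= 2 co-observed rows)")
  l <- table$left[both]
  r <- table$right[both]
  if (stats::var(l) == 0 || stats::var(r) == 0) {
    stop("insufficient binocular overlap (zero predictor variance)")
  }
  if (n_fit < min_overlap) {
    warning(sprintf("cross-eye regression fitted on only %d co-observed rows",
                    n_fit), call. = FALSE)
  }
  f_lr <- stats::lm.fit(cbind(1, l), r)$coefficients
  f_rl <- stats::lm.fit(cbind(1, r), l)$coefficients
  structure(list(
    slope_lr = unname(f_lr[2]), intercept_lr = unname(f_lr[1]),
    slope_rl = unname(f_rl[2]), intercept_rl = unname(f_rl[1]),
    n_fit = n_fit,
    r_squared = stats::cor(l, r)^2
  ), class = "cross_eye_model")
}

#' @export
print.cross_eye_model <- function(x, ...) {
  cat("Cross-eye linear regression (per recording)\n")
  cat(sprintf("  right = %.4f * left + %.4f\n", x$slope_lr, x$intercept_lr))
  cat(sprintf("  left  = %.4f * right + %.4f\n", x$slope_rl, x$intercept_rl))
  cat(sprintf("  fitted on %d co-observed rows, r^2 = %.4f\n",
              x$n_fit, x$r_squared))
  invisible(x)
}

#' Impute a missing eye from the other eye
#'
#' Rows where exactly one eye is observed get the other predicted through
#' the appropriate direction of the cross-eye model and flagged
#' `"imputed"`.  Observed values are never overwritten; rows with both
#' eyes missing stay missing (they keep the time base for later joins).
#'
#' @param table a `binocular_table`.
#' @param model a `cross_eye_model` from [fit_cross_eye()].
#' @return The imputed `binocular_table`.
#' @export
impute_missing_eye <- function(table, model) {
  only_l <- !is.na(table$left) & is.na(table$right)
  only_r <- is.na(table$left) & !is.na(table$right)
  table$right[only_l] <- model$slope_lr * table$left[only_l] + model$intercept_lr
  table$right_provenance[only_l] <- "imputed"
  table$left[only_r] <- model$slope_rl * table$right[only_r] + model$intercept_rl
  table$left_provenance[only_r] <- "imputed"
  table
}

#' Mean pupil diameter
#'
#' Fills the `mean` column with `(left + right) / 2` wherever both eyes are
#' present (after imputation that is every row where at least one eye was
#' observed); rows with both eyes missing keep a missing mean.
#'
#' @param table a `binocular_table`, normally after [impute_missing_eye()].
#' @return The table with its `mean` column filled.
#' @export
mean_pupil <- function(table) {
  both <- !is.na(table$left) & !is.na(table$right)
  table$mean[both] <- (table$left[both] + table$right[both]) / 2
  table
}
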