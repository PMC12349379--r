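#' Upsample an eye trace onto a regular millisecond grid
#'
#' Reconstructs the cleaned, outlier-free trace on a regular grid at
#' `target_rate` Hz (default 1000 Hz, i.e. one sample per millisecond)
#' using the shape-preserving PCHIP interpolant.  The grid runs from
#' `ceiling(t_first)` to `floor(t_last)` in steps of `1000/target_rate` ms,
#' so grids built from different traces are commensurable and can later be
#' joined exactly.  No extrapolation is performed beyond the observed span.
#'
#' Grid points that coincide with an observation keep provenance
#' `"observed"`; all others are flagged `"interpolated"`.
#'
#' @param trace an `eye_trace` with >= 2 samples, cleaned and outlier-free.
#' @param target_rate output rate in Hz (default 1000).
#' @param method interpolation method; `"pchip"` (default), `"linear"`,
#'   `"cubic_spline"`, `"akima"` or `"previous"`.
#' @return An `eye_trace` on the regular grid.
#' @export
upsample <- function(trace, target_rate = 1000, method = "pchip") {
  stopifnot(target_rate > 0)
  if (nrow(trace) < 2) stop("upsample: need at least 2 samples")
  step <- 1000 / target_rate
  t0 <- ceiling(trace$time[1] / step) * step
  t1 <- floor(trace$time[nrow(trace)] / step) * step
  if (t1 < t0) stop("upsample: trace span shorter than one grid step")
  grid <- seq(t0, t1, by = step)
  vals <- interp_values(trace$time, trace$diameter, grid, method)
  prov <- rep("interpolated", length(grid))
  hit <- findInterval(grid, trace$time)
  coincide <- hit >= 1 & abs(grid - trace$time[pmax(hit, 1)]) < 1e-9
  prov[coincide] <- "observed"
  eye_trace(grid, vals, eye = attr(trace, "eye"), provenance = prov)
}

#' Mask interpolated values that span long gaps
#'
#' Interpolation across a long dropout (e.g. a blink with its edges
#' removed) fabricates signal.  For every pair of consecutive samples in
#' the *original* (pre-interpolation) trace whose spacing strictly exceeds
#' `max_gap_ms`, all grid points strictly inside that interval are removed
#' from the upsampled trace.  Grid points that coincide with an original
#' observation are never removed; a gap of exactly `max_gap_ms` is kept.
#'
#' @param upsampled the output of [upsample()].
#' @param original the `eye_trace` the interpolant was built from.
#' @param max_gap_ms longest original inter-sample gap that may be bridged
#'   (default 250 ms).
#' @return The masked `eye_trace`, with attribute `n_removed`.
#' @export
mask_long_gaps <- function(upsampled, original, max_gap_ms = 250) {
  stopifnot(max_gap_ms > 0)
  if (nrow(original) < 2 || nrow(upsampled) == 0) return(upsampled)
  ot <- original$time
  gaps <- diff(ot)
  k <- findInterval(upsampled$time, ot)
  k_ok <- pmin(pmax(k, 1L), length(gaps))
  inside <- upsampled$time > ot[k_ok] & upsampled$time < ot[k_ok + 1]
  drop <- inside & gaps[k_ok] > max_gap_ms
  out <- rebuild_trace(upsampled, which(!drop))
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Compare interpolation methods by random holdout
#'
#' Randomly holds out a fraction of *interior* samples (the endpoints stay
#' in the fit so no method needs to extrapolate), fits each method on the
#' remaining samples, predicts at the held-out times, and scores each
#' method by root-mean-squared error and maximum absolute error against the
#' held-out values.
#'
#' @param trace an `eye_trace` with at least 20 samples.
#' @param holdout_fraction fraction of samples to hold out, in (0, 0.5).
#' @param methods character vector of methods (see [upsample()]).
#' @param seed integer seed for the holdout draw.
#' @return A data frame with columns `method`, `rmse`, `max_error` (mm).
#' @export
compare_interpolators <- function(trace, holdout_fraction = 0.1,
                                  methods = c("pchip", "linear",
                                              "cubic_spline", "previous"),
                                  seed = 1) {
  n <- nrow(trace)
  if (n < 20) stop("compare_interpolators: trace too short (need >= 20)")
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5)
  n_hold <- max(1L, round(holdout_fraction * n))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  hold <- sort(sample(2:(n - 1), n_hold))
  fit_idx <- setdiff(seq_len(n), hold)
  t_fit <- trace$time[fit_idx]
  d_fit <- trace$diameter[fit_idx]
  t_hold <- trace$time[hold]
  d_hold <- trace$diameter[hold]
  res <- lapply(methods, function(m) {
    pred <- interp_values(t_fit, d_fit, t_hold, m)
    err <- pred - d_hold
    data.frame(method = m,
               rmse = sqrt(mean(err^2)),
               max_error = max(abs(err)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
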