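# Independent brute-force reference implementations, written as plain
# loops from the formula definitions.  They deliberately share no code
# with the package internals (including the median, computed by sorting)
# so they can serve as oracles.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) {
  m <- oracle_median(x)
  dev <- numeric(length(x))
  for (i in seq_along(x)) dev[i] <- abs(x[i] - m)
  oracle_median(dev)
}

# max of backward/forward absolute difference quotients, one-sided at ends
oracle_speed <- function(t, d) {
  n <- length(t)
  out <- numeric(n)
  for (i in seq_len(n)) {
    back <- if (i > 1) abs(d[i] - d[i - 1]) / (t[i] - t[i - 1]) else NA
    fwd <- if (i < n) abs(d[i + 1] - d[i]) / (t[i + 1] - t[i]) else NA
    out[i] <- max(back, fwd, na.rm = TRUE)
  }
  out
}

# indices removed by the dilation-speed detector (single pass)
oracle_speed_outliers <- function(t, d, n_mad = 20) {
  sp <- oracle_speed(t, d)
  thr <- oracle_median(sp) + n_mad * oracle_mad(sp)
  which(sp > thr)
}

# trailing moving average with shrinking warm-up
oracle_ma <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - k + 1)
    s <- 0
    for (j in lo:i) s <- s + x[j]
    out[i] <- s / (i - lo + 1)
  }
  out
}

# indices removed by the moving-average deviation detector (single pass)
oracle_local_outliers <- function(x, k = 23, n_ma = 18) {
  ma <- oracle_ma(x, k)
  dev <- abs(x - ma)
  thr <- n_ma * oracle_median(dev)
  which(dev > thr)
}

# a random irregular trace with plausible diameters
make_random_trace <- function(n, seed, eye = "left") {
  set.seed(seed)
  t <- cumsum(runif(n, 5, 12))
  d <- 4 + cumsum(rnorm(n, 0, 0.02))
  eye_trace(t, d, eye = eye)
}

# a smooth (noise- and artifact-free) 120 Hz pupil trace
make_smooth_trace <- function(seed, duration_s = 30) {
  spec <- synthetic_spec(
    duration_s = duration_s, measurement_noise_sd = 0,
    eye_coupling = list(slope = 0.9, intercept = 0.3, noise_sd = 0),
    blink_rate_per_min = 0, occlusion_spike_rate_per_min = 0,
    out_of_range_rate_per_min = 0, duplicate_timestamp_rate = 0,
    seed = seed)
  split_streams(generate_recording(spec)$table)$left
}

# write the three-row wide-table example (facial-only row followed by two
# pupil-only rows, "Nan" sentinels) to a temp CSV and return its path
write_example_csv <- function() {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(
    "Timestamp,ET_PupilLeft,ET_PupilRight,Facial Expression1,Facial Expression 2",
    "63212,Nan,Nan,27.53,0.31",
    "63216.17,5.150,5.023,Nan,Nan",
    "63257.62,5.148,5.02,Nan,Nan"
  ), path)
  path
}
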