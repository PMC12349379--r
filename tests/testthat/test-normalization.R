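make_binoc <- function(t, left, right) {
  align_eyes(eye_trace(t[!is.na(left)], left[!is.na(left)], eye = "left"),
             eye_trace(t[!is.na(right)], right[!is.na(right)], eye = "right"))
}

test_that("the first consecutive binocular stretch of 400 ms is found", {
  # fully valid 120 Hz recording: window starts at the first timestamp
  t <- round((0:240) * 8.333)
  b <- make_binoc(t, rep(4, 241), rep(3.9, 241))
  w <- find_baseline_window(b)
  expect_equal(w[1], t[1])
  expect_gte(w[2] - w[1], 400)

  # a blink every 300 ms leaves no 400 ms clean run
  t2 <- seq(0, 2000, by = 8)
  left <- rep(4, length(t2)); left[t2 %% 300 < 8] <- NA
  b2 <- make_binoc(t2, left, rep(3.9, length(t2)))
  expect_error(find_baseline_window(b2), "no valid baseline period")

  # known first clean run at [1200, 1700] ms is returned exactly
  t3 <- seq(0, 3000, by = 10)
  left3 <- rep(NA_real_, length(t3))
  left3[t3 >= 1200 & t3 <= 1700] <- 4
  left3[t3 >= 2000] <- 4
  b3 <- make_binoc(t3, left3, rep(3.9, length(t3)))
  expect_equal(find_baseline_window(b3), c(1200, 1700))
})

test_that("a long inter-sample gap breaks consecutiveness", {
  t <- c(seq(0, 300, by = 10), seq(400, 900, by = 10))  # 100 ms hole
  b <- make_binoc(t, rep(4, length(t)), rep(4, length(t)))
  w <- find_baseline_window(b, min_duration_ms = 400, max_gap_ms = 15)
  expect_equal(w, c(400, 900))   # the run after the hole qualifies first
})

test_that("the baseline averages the processed series over the window", {
  t <- 0:999
  b <- mean_pupil(make_binoc(t, rep(4.2, 1000), rep(4.2, 1000)))
  res <- compute_baseline(b, c(0, 400))
  expect_equal(res$baseline_mm, 4.2)

  ramp <- seq(3, 5, length.out = 1000)
  b2 <- mean_pupil(make_binoc(t, ramp, ramp))
  res2 <- compute_baseline(b2, c(0, 999))
  expect_equal(res2$baseline_mm, (3 + 5) / 2)   # midpoint of a linear ramp

  set.seed(16)
  vals <- 4 + rnorm(1000, 0, 0.1)
  b3 <- mean_pupil(make_binoc(t, vals, vals))
  win <- c(100, 399)
  res3 <- compute_baseline(b3, win)
  expect_equal(res3$baseline_mm, mean(vals[t >= 100 & t <= 399]))
  expect_error(compute_baseline(b3, c(2000, 2400)), "no processed samples")
})

test_that("normalization is baseline-relative and invertible", {
  expect_equal(normalize_dilation(4.0, 4.0), 0)
  expect_equal(normalize_dilation(5.0, 4.0), 0.25)
  expect_equal(normalize_dilation(3.0, 4.0), -0.25)
  expect_true(is.na(normalize_dilation(NA, 4.0)))
  expect_error(normalize_dilation(4, 0), "positive")
  expect_error(normalize_dilation(4, -1), "positive")

  set.seed(17)
  x <- runif(500, 2.5, 7.5)
  b <- 4.3
  expect_lt(max(abs(b * (1 + normalize_dilation(x, b)) - x)), 1e-12)
})

test_that("mean normalized dilation matches its algebraic identity", {
  expect_equal(mean_normalized_dilation(rep(0, 10)), 0)
  expect_equal(mean_normalized_dilation(c(0.1, -0.1)), 0)
  expect_error(mean_normalized_dilation(c(NA_real_, NA_real_)), "all values")

  set.seed(18)
  x <- runif(300, 3, 6)
  b <- 4.1
  expect_equal(mean_normalized_dilation(normalize_dilation(x, b)),
               mean(x) / b - 1, tolerance = 1e-12)
})

test_that("the generator's baseline is recovered from its quiet period", {
  spec <- synthetic_spec(duration_s = 20, blink_rate_per_min = 0,
                         occlusion_spike_rate_per_min = 0,
                         out_of_range_rate_per_min = 0,
                         duplicate_timestamp_rate = 0,
                         hippus_amplitude_mm = 0.02, seed = 19)
  rec <- generate_recording(spec)
  s <- split_streams(rec$table)
  b <- mean_pupil(align_eyes(round_timestamps(s$left, 1),
                             round_timestamps(s$right, 1)))
  w <- find_baseline_window(b)
  res <- compute_baseline(mean_pupil(b), w)
  # true mean-series baseline under the coupling, within noise standard error
  truth_mean <- (1 + spec$eye_coupling$slope) / 2 * spec$baseline_mm +
    spec$eye_coupling$intercept / 2
  n_win <- sum(b$timestamp >= w[1] & b$timestamp <= w[2])
  se <- spec$measurement_noise_sd / sqrt(n_win)
  expect_lt(abs(res$baseline_mm - truth_mean), 0.02 + 3 * se)
})
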