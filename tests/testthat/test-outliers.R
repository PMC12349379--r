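test_that("dilation speed is the max of one-sided difference quotients", {
  # hand evaluation: interior sample takes max(0.02, 0.01)
  tr <- eye_trace(c(0, 10, 20), c(3.0, 3.2, 3.1))
  expect_equal(dilation_speed(tr), c(0.02, 0.02, 0.01))

  const <- eye_trace(seq(0, 100, by = 10), rep(4, 11))
  expect_equal(dilation_speed(const), rep(0, 11))

  expect_error(dilation_speed(eye_trace(0, 4)), "insufficient samples")
})

test_that("dilation speed matches the loop oracle on random traces", {
  for (seed in c(101, 102, 103)) {
    tr <- make_random_trace(500, seed)
    expect_equal(dilation_speed(tr), oracle_speed(tr$time, tr$diameter))
  }
})

test_that("raw MAD follows its definition, without a consistency constant", {
  expect_equal(mad_raw(rep(2.5, 9)), 0)
  expect_equal(mad_raw(c(1, 2, 3, 4, 100)), 1)  # median 3, |dev| = 2,1,0,1,97
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(5:200, 1))
    expect_equal(mad_raw(x), oracle_mad(x))
    # differs from stats::mad unless rescaled
    expect_equal(mad_raw(x) * 1.4826, stats::mad(x), tolerance = 1e-12)
  }
  expect_error(mad_raw(numeric(0)), "empty")
})

test_that("speed threshold is median + n * MAD", {
  sp <- c(0.0005, 0.001, 0.0015)   # median 0.001, MAD 0.0005
  expect_equal(speed_threshold(sp, n_mad = 20), 0.011)
  expect_equal(speed_threshold(rep(0, 5)), 0)
  set.seed(42)
  sp2 <- abs(rnorm(500, 0, 0.002))
  expect_gte(speed_threshold(sp2), median(sp2))
})

test_that("speed outlier removal matches the brute-force selection", {
  # a smooth trace loses nothing
  t <- seq(0, 5000, by = 8.333)
  smooth <- eye_trace(t, 4 + 0.3 * sin(2 * pi * t / 4000))
  expect_equal(nrow(remove_speed_outliers(smooth)), length(t))

  # one 2 mm step over a single 8.33 ms frame is removed
  d <- smooth$diameter
  d[300] <- d[300] - 2
  out <- remove_speed_outliers(eye_trace(t, d))
  expect_false(t[300] %in% out$time)

  for (seed in c(201, 202, 203, 204)) {
    tr <- make_random_trace(800, seed)
    kept <- remove_speed_outliers(tr)
    removed_oracle <- oracle_speed_outliers(tr$time, tr$diameter, 20)
    expect_equal(setdiff(seq_len(800), match(kept$time, tr$time)),
                 removed_oracle)
  }
})

test_that("moving average handles warm-up, identity and constants", {
  expect_equal(moving_average(c(5, 7, 2), 1), c(5, 7, 2))
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1, 1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(3.3, 50), 23), rep(3.3, 50))
  expect_equal(moving_average(numeric(0), 5), numeric(0))
  set.seed(51)
  x <- rnorm(300)
  expect_equal(moving_average(x, 23), oracle_ma(x, 23))
  # centered window of width 1 is also the identity
  expect_equal(moving_average(x, 1, align = "centered"), x)
})

test_that("local outlier removal matches the brute-force selection", {
  const <- eye_trace(seq(0, 400, by = 8), rep(4, 51))
  expect_equal(nrow(remove_local_outliers(const, warn_window = FALSE)),
               51)  # threshold 0, strict inequality keeps everything

  # a single 0.5 mm occlusion-like dip is removed, neighbours retained
  t <- seq(0, 8000, by = 8.333)
  set.seed(61)
  d <- 4 + 0.2 * sin(2 * pi * t / 5000) + rnorm(length(t), 0, 0.01)
  d[500] <- d[500] - 0.5
  out <- remove_local_outliers(eye_trace(t, d), warn_window = FALSE)
  expect_false(t[500] %in% out$time)
  expect_true(all(t[c(499, 501)] %in% out$time))

  for (seed in c(301, 302, 303)) {
    tr <- make_random_trace(700, seed)
    kept <- remove_local_outliers(tr, warn_window = FALSE)
    removed_oracle <- oracle_local_outliers(tr$diameter, 23, 18)
    expect_equal(setdiff(seq_len(700), match(kept$time, tr$time)),
                 removed_oracle)
  }
})

test_that("both detectors are monotone in n and never alter survivors", {
  for (seed in c(401, 402)) {
    tr <- make_random_trace(600, seed)
    for (pair in list(c(5, 10), c(10, 20), c(18, 36))) {
      rem_lo <- attr(remove_speed_outliers(tr, n_mad = pair[1]), "removed_time")
      rem_hi <- attr(remove_speed_outliers(tr, n_mad = pair[2]), "removed_time")
      expect_true(all(rem_hi %in% rem_lo))
      rem_lo <- attr(remove_local_outliers(tr, n_ma = pair[1],
                                           warn_window = FALSE), "removed_time")
      rem_hi <- attr(remove_local_outliers(tr, n_ma = pair[2],
                                           warn_window = FALSE), "removed_time")
      expect_true(all(rem_hi %in% rem_lo))
    }
    kept <- remove_speed_outliers(tr)
    expect_equal(kept$diameter, tr$diameter[match(kept$time, tr$time)])
  }
})

test_that("the window validator warns outside the blink span", {
  tr <- make_random_trace(200, seed = 71)   # ~8.5 ms median period
  expect_warning(remove_local_outliers(tr, window_k = 5), "150-400 ms")
  expect_warning(remove_local_outliers(tr, window_k = 100), "150-400 ms")
  expect_silent(remove_local_outliers(tr, window_k = 23))
})
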