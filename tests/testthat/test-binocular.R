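test_that("outer-join alignment keeps the union of timestamps", {
  l <- eye_trace(0:9, rep(4, 10), eye = "left")
  r <- eye_trace(0:9, rep(3.9, 10), eye = "right")
  expect_equal(nrow(align_eyes(l, r)), 10)

  r2 <- eye_trace(10:19, rep(3.9, 10), eye = "right")
  expect_equal(nrow(align_eyes(l, r2)), 20)   # disjoint grids

  set.seed(12)
  tl <- sort(sample(0:500, 120)); tr <- sort(sample(0:500, 150))
  b <- align_eyes(eye_trace(tl, rep(4, 120), eye = "left"),
                  eye_trace(tr, rep(4, 150), eye = "right"))
  expect_equal(b$timestamp, sort(union(tl, tr)))
  # every observed pair survives unchanged
  expect_equal(b$left[match(tl, b$timestamp)], rep(4, 120))
  expect_error(align_eyes(eye_trace(numeric(0), numeric(0)),
                          eye_trace(numeric(0), numeric(0), eye = "right")),
               "empty")
})

test_that("cross-eye regression recovers affine relations exactly", {
  t <- 0:99
  l <- 4 + 0.3 * sin(t / 10)
  b <- align_eyes(eye_trace(t, l, eye = "left"),
                  eye_trace(t, l, eye = "right"))
  m_id <- fit_cross_eye(b)
  expect_equal(m_id$slope_lr, 1, tolerance = 1e-9)
  expect_equal(m_id$intercept_lr, 0, tolerance = 1e-9)

  b2 <- align_eyes(eye_trace(t, l, eye = "left"),
                   eye_trace(t, 0.9 * l + 0.3, eye = "right"))
  m <- fit_cross_eye(b2)
  expect_equal(m$slope_lr, 0.9, tolerance = 1e-9)
  expect_equal(m$intercept_lr, 0.3, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$n_fit, 100)
})

test_that("degenerate overlap is rejected and sparse overlap warned about", {
  b <- align_eyes(eye_trace(0:1, c(4, 4), eye = "left"),
                  eye_trace(2:3, c(4, 4), eye = "right"))
  expect_error(fit_cross_eye(b), "insufficient binocular overlap")
  bc <- align_eyes(eye_trace(0:9, rep(4, 10), eye = "left"),
                   eye_trace(0:9, rep(4, 10), eye = "right"))
  expect_error(fit_cross_eye(bc), "zero predictor variance")
  bs <- align_eyes(eye_trace(0:9, 4 + (0:9) / 10, eye = "left"),
                   eye_trace(0:9, 4 - (0:9) / 10, eye = "right"))
  expect_warning(fit_cross_eye(bs), "only 10 co-observed rows")
})

test_that("regression recovers noisy coupling within 3 standard errors", {
  set.seed(13)
  n <- 5000
  l <- rnorm(n, 4.5, 0.6)
  r <- 0.9 * l + 0.3 + rnorm(n, 0, 0.05)
  b <- align_eyes(eye_trace(seq_len(n), l, eye = "left"),
                  eye_trace(seq_len(n), r, eye = "right"))
  m <- fit_cross_eye(b)
  se <- summary(lm(r ~ l))$coefficients[, "Std. Error"]
  expect_lt(abs(m$slope_lr - 0.9), 3 * se["l"])
  expect_lt(abs(m$intercept_lr - 0.3), 3 * se["(Intercept)"])
})

test_that("imputation fills only the missing eye and never overwrites", {
  t <- 0:4
  b <- align_eyes(eye_trace(c(0, 1, 2, 4), c(4.0, 4.1, 4.0, 4.2), eye = "left"),
                  eye_trace(c(0, 1, 3, 4), c(3.9, 4.0, 3.8, 4.1), eye = "right"))
  model <- structure(list(slope_lr = 0.9, intercept_lr = 0.3,
                          slope_rl = 1 / 0.9, intercept_rl = -0.3 / 0.9,
                          n_fit = 4, r_squared = 1),
                     class = "cross_eye_model")
  out <- impute_missing_eye(b, model)
  # left = 4.0 with right missing imputes right = 0.9*4 + 0.3 = 3.9
  expect_equal(out$right[out$timestamp == 2], 3.9)
  expect_equal(out$right_provenance[out$timestamp == 2], "imputed")
  expect_equal(out$left[out$timestamp == 3], (3.8 - 0.3) / 0.9)
  # observed cells unchanged
  expect_equal(out$right[out$timestamp == 0], 3.9)
  expect_equal(out$left[out$timestamp == 4], 4.2)
  # a table with no single-eye rows is untouched
  full <- align_eyes(eye_trace(t, rep(4, 5), eye = "left"),
                     eye_trace(t, 4 + t / 10, eye = "right"))
  expect_equal(as.data.frame(impute_missing_eye(full, model)),
               as.data.frame(full))
})

test_that("imputation error stays near the generative noise level", {
  set.seed(14)
  n <- 5000
  l <- 4 + 0.4 * sin(seq_len(n) / 300) + rnorm(n, 0, 0.02)
  r_true <- 0.9 * l + 0.3 + rnorm(n, 0, 0.05)
  drop <- sort(sample(n, n / 5))            # 20% right-eye deletions
  r_obs <- r_true; r_obs[drop] <- NA
  b <- align_eyes(eye_trace(seq_len(n), l, eye = "left"),
                           eye_trace(seq_len(n)[-drop], r_obs[-drop],
                                     eye = "right"))
  m <- fit_cross_eye(b)
  out <- impute_missing_eye(b, m)
  rmse <- sqrt(mean((out$right[drop] - r_true[drop])^2))
  expect_lte(rmse, 2 * 0.05)
})

test_that("mean pupil is the arithmetic mean where both eyes exist", {
  b <- align_eyes(eye_trace(c(0, 1, 2), c(5.0, 4.0, 4.4), eye = "left"),
                  eye_trace(c(0, 1, 3), c(5.0, 3.9, 4.0), eye = "right"))
  out <- mean_pupil(b)
  expect_equal(out$mean[out$timestamp == 0], 5.0)
  expect_equal(out$mean[out$timestamp == 1], 3.95)
  expect_true(is.na(out$mean[out$timestamp == 2]))
  # elementwise against a loop
  loop <- sapply(seq_len(nrow(out)), function(i) {
    if (!is.na(out$left[i]) && !is.na(out$right[i]))
      (out$left[i] + out$right[i]) / 2 else NA_real_
  })
  expect_equal(out$mean, loop)
})

test_that("noiseless affine eyes yield the analytic mean despite missingness", {
  t <- 0:499
  l_full <- 4 + 0.3 * sin(t / 40)
  r_full <- 0.9 * l_full + 0.3
  set.seed(15)
  miss_l <- sample(t[c(-1, -500)], 100)
  miss_r <- sample(setdiff(t, miss_l), 100)
  b <- align_eyes(eye_trace(setdiff(t, miss_l),
                            l_full[!t %in% miss_l], eye = "left"),
                  eye_trace(setdiff(t, miss_r),
                            r_full[!t %in% miss_r], eye = "right"))
  out <- mean_pupil(impute_missing_eye(b, fit_cross_eye(b)))
  expect_equal(out$mean, (l_full + r_full) / 2, tolerance = 1e-9)
})
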