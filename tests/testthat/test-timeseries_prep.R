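test_that("linear detrending removes exact trends and is idempotent", {
  n <- 50
  ramp <- 2 * seq_len(n) + 1
  set.seed(1)
  x <- cbind(ramp, rnorm(n))
  ts <- parcel_ts(x, tr = 1)
  d1 <- linear_detrend(ts)
  expect_lt(max(abs(d1$data[, 1])), 1e-10)
  d2 <- linear_detrend(d1)
  expect_lt(max(abs(d2$data - d1$data)), 1e-10)
  expect_lt(abs(sum(d1$data[, 2] * seq_len(n))), 1e-8)
  expect_lt(max(abs(colMeans(d1$data))), 1e-12)
  expect_error(linear_detrend(parcel_ts(matrix(1:4, 2), 1)), "3 frames")
})

test_that("Friston-24 expansion has the documented block layout", {
  p <- matrix(seq_len(10), 10, 6)
  f <- expand_friston24(p)
  expect_equal(ncol(f), 24)
  expect_equal(f[, 7], c(0, 1:9))      # lag block, zero-padded
  expect_equal(f[, 13], (1:10)^2)      # square block
  expect_equal(f[, 19], c(0, 1:9)^2)   # lagged square block
  expect_equal(expand_friston24(matrix(0, 5, 6)), matrix(0, 5, 24),
               ignore_attr = TRUE)
  expect_error(expand_friston24(matrix(0, 5, 5)), "6 columns")
})

test_that("nuisance regression projects out confounds exactly", {
  set.seed(2)
  n <- 100
  sig <- rnorm(n)
  ts <- parcel_ts(cbind(sig, rnorm(n)), tr = 1)
  r <- nuisance_regress(ts, cbind(sig))
  expect_lt(max(abs(r$data[, 1])), 1e-10)

  # orthonormal confounds: variance drops by exactly the projected share
  q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  y <- rnorm(n)
  ts2 <- parcel_ts(cbind(y), tr = 1)
  r2 <- nuisance_regress(ts2, q)
  qc <- qr.Q(qr(cbind(1, q)))
  rss_expected <- sum(y^2) - sum(crossprod(qc, y)^2)
  expect_lt(abs(sum(r2$data^2) - rss_expected), 1e-6)
  expect_lt(max(abs(crossprod(q, r2$data))), 1e-8)

  r0 <- nuisance_regress(ts2, NULL)
  expect_equal(as.numeric(r0$data), y - mean(y))

  expect_error(nuisance_regress(ts2, cbind(a = y, b = y)), "rank deficient")
})

test_that("Butterworth filters pass and stop the right frequencies", {
  tr <- 0.72
  n <- 1000
  t <- (seq_len(n) - 1) * tr
  inband <- sin(2 * pi * 0.05 * t)
  outband <- sin(2 * pi * 0.5 * t)
  ts <- parcel_ts(cbind(inband, outband, 1 + 0 * t + rnorm(n, 0, 1e-6)),
                  tr = tr)
  f <- bandpass_filter(ts)
  mid <- 200:800   # ignore filter edge transients
  amp_in <- sd(f$data[mid, 1]) / sd(inband[mid])
  amp_out <- sd(f$data[mid, 2]) / sd(outband[mid])
  expect_gte(amp_in, 0.9)
  expect_lte(amp_out, 0.1)
  expect_lt(max(abs(f$data[mid, 3])), 0.05)   # DC removed

  h <- highpass_filter(ts, 0.01)
  expect_gte(sd(h$data[mid, 2]) / sd(outband[mid]), 0.9)
  expect_error(bandpass_filter(parcel_ts(cbind(inband), tr = 2),
                               0.01, 0.3), "inside")
})

test_that("task regressors are HRF-convolved boxcars per condition", {
  tr <- 0.72; n <- 200
  expect_equal(ncol(build_task_regressors(
    data.frame(onset = numeric(0), duration = numeric(0),
               condition = character(0)), tr, n)), 0)

  ev <- data.frame(onset = 20, duration = 10, condition = "A")
  X <- build_task_regressors(ev, tr, n)
  t <- (seq_len(n) - 1) * tr
  expect_lt(max(abs(X[t < 20, 1])), 1e-12)      # support after onset only
  peak_t <- t[which.max(X[, 1])]
  expect_gte(peak_t, 20 + 3); expect_lte(peak_t, 20 + 10 + 8)

  ev2 <- rbind(ev, data.frame(onset = 80, duration = 10, condition = "B"))
  X2 <- build_task_regressors(ev2, tr, n)
  expect_equal(X2[, "A"], X[, 1])

  evo <- data.frame(onset = c(10, 15), duration = c(10, 10),
                    condition = "A")
  expect_warning(build_task_regressors(evo, tr, n), "overlapping")
})

test_that("background residuals drop fixation frames after a full-run fit", {
  tr <- 0.72; n <- 250
  ev <- data.frame(onset = c(0, 36, 72, 144),
                   duration = c(36, 36, 72, 36),
                   condition = c("A", "fixation", "A", "fixation"))
  set.seed(3)
  ts <- parcel_ts(matrix(rnorm(n * 3), n), tr)
  bg <- task_background_residuals(ts, ev)
  mid <- (seq_len(n) - 1) * tr + tr / 2
  in_fix <- (mid >= 36 & mid < 72) | (mid >= 144 & mid < 180)
  expect_equal(nrow(bg$data), sum(!in_fix))
  expect_equal(bg$frame_keep_mask, !in_fix)

  # no fixation: frame count unchanged, residuals orthogonal to regressors
  ev2 <- ev[ev$condition != "fixation", ]
  bg2 <- task_background_residuals(ts, ev2)
  expect_equal(nrow(bg2$data), n)
  X <- build_task_regressors(ev2, tr, n)
  expect_lt(max(abs(crossprod(X, bg2$data))), 1e-8)

  # all-fixation run is degenerate
  expect_error(task_background_residuals(
    ts, data.frame(onset = 0, duration = n * tr, condition = "fixation")),
    "fixation")
})

test_that("run concatenation standardizes per run", {
  set.seed(4)
  r1 <- parcel_ts(matrix(rnorm(200, mean = 5), 100), tr = 1, run_id = "a")
  r2 <- parcel_ts(matrix(rnorm(200, mean = -5), 100), tr = 1, run_id = "b")
  cc <- concatenate_runs(list(r1, r2))
  expect_equal(nrow(cc$data), 200)
  expect_lt(max(abs(colMeans(cc$data))), 1e-10)
  one <- concatenate_runs(list(r1))
  expect_equal(apply(one$data, 2, sd), rep(1, 2), ignore_attr = TRUE)
  r3 <- parcel_ts(matrix(rnorm(300), 100), tr = 1)
  expect_error(concatenate_runs(list(r1, r3)), "region count")
})
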