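test_that("ROI extraction averages the region per frame", {
  mov <- array(7, dim = c(16, 16, 10))
  tr <- extract_roi_trace(mov, center = c(8, 8), side_px = 5,
                          frame_interval = 1)
  expect_equal(tr$intensity, rep(7, 10))

  idx <- array(0, dim = c(16, 16, 10))
  for (i in 1:10) idx[, , i] <- i - 1
  tr2 <- extract_roi_trace(idx, center = c(8, 8), side_px = 5,
                           frame_interval = 0.5)
  expect_equal(tr2$intensity, 0:9)
  expect_equal(tr2$time_s, (0:9) * 0.5)

  expect_error(extract_roi_trace(mov, center = c(1, 1), side_px = 9,
                                 frame_interval = 1),
               class = "curvesense_geometry_error")
  expect_error(extract_roi_trace(mov[, , 1:4, drop = FALSE],
                                 center = c(8, 8), side_px = 3,
                                 frame_interval = 1),
               class = "curvesense_invalid_parameters")
})

test_that("detrending removes trends and preserves oscillations", {
  t <- seq(0, 100, by = 1)
  ramp <- tibble::tibble(time_s = t, intensity = 3 + 0.5 * t)
  out <- detrend_trace(ramp, window = 25)
  interior <- out$intensity[14:(length(t) - 13)]
  expect_lt(max(abs(interior)), 1e-9)

  const <- tibble::tibble(time_s = t, intensity = rep(2, length(t)))
  expect_equal(detrend_trace(const, 25)$intensity, rep(0, length(t)))

  ## pure sinusoid, window = one period: amplitude attenuation < 5%
  sine <- tibble::tibble(time_s = t, intensity = sin(2 * pi * t / 25))
  ds <- detrend_trace(sine, window = 25)
  interior <- 14:(length(t) - 13)
  amp <- max(abs(ds$intensity[interior]))
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)

  expect_error(detrend_trace(sine, window = 1),
               class = "curvesense_invalid_parameters")
})

test_that("self-correlation and antisymmetry hold", {
  pr <- wave_pair(2, frame_interval = 1, noise_sd = 0.1, seed = 3)
  self <- xcorr_lag(pr$ref, pr$ref, max_lag = 10)
  expect_equal(self$lag, 0)
  expect_equal(self$peak_correlation, 1, tolerance = 1e-12)

  ab <- xcorr_lag(pr$lagged, pr$ref, max_lag = 10)
  ba <- xcorr_lag(pr$ref, pr$lagged, max_lag = 10)
  expect_equal(ab$lag, -ba$lag)
})

test_that("xcorr_lag equals the brute-force lag scan to machine precision", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(40:80, 1)
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    a <- tibble::tibble(time_s = seq_len(n) - 1, intensity = x)
    b <- tibble::tibble(time_s = seq_len(n) - 1, intensity = y)
    kmax <- sample(5:15, 1)
    ps <- xcorr_lag(a, b, max_lag = kmax, detrend = FALSE)
    bf <- bf_xcorr(x, y, kmax)
    expect_equal(ps$correlation_curve$correlation, bf$r,
                 tolerance = 1e-12)
    expect_equal(ps$lag, bf_best_lag(x, y, kmax))
  }
})

test_that("the estimated lag is invariant under affine intensity maps", {
  pr <- wave_pair(3, frame_interval = 1, noise_sd = 0.1, seed = 5)
  base <- xcorr_lag(pr$lagged, pr$ref, max_lag = 10, subsample = TRUE)
  scaled <- pr$lagged
  scaled$intensity <- 4.2 * scaled$intensity + 17
  tr <- xcorr_lag(scaled, pr$ref, max_lag = 10, subsample = TRUE)
  expect_equal(tr$lag, base$lag, tolerance = 1e-9)
  expect_equal(tr$peak_correlation, base$peak_correlation,
               tolerance = 1e-9)
})

test_that("a 5 s offset at 1 s sampling and 10% noise is recovered", {
  errs <- vapply(1:20, function(seed) {
    pr <- wave_pair(5, frame_interval = 1, noise_sd = 0.1, seed = seed)
    xcorr_lag(pr$lagged, pr$ref, max_lag = 10)$lag - 5
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.5)
})

test_that("degenerate traces raise informative errors", {
  n <- 50
  flat <- tibble::tibble(time_s = seq_len(n) - 1, intensity = rep(1, n))
  wig <- tibble::tibble(time_s = seq_len(n) - 1, intensity = sin(1:n))
  expect_error(xcorr_lag(flat, wig, max_lag = 5, detrend = FALSE),
               class = "curvesense_degenerate_signal")
  short <- tibble::tibble(time_s = (seq_len(n) - 1) * 2,
                          intensity = sin(1:n))
  expect_error(xcorr_lag(short, wig, max_lag = 5),
               class = "curvesense_grid_error")
  expect_error(xcorr_lag(wig, wig, max_lag = 30),
               class = "curvesense_invalid_parameters")
})

test_that("peak alignment reproduces construction-time shifts", {
  pr0 <- wave_pair(0, frame_interval = 0.5, noise_sd = 0, seed = 7)
  ap0 <- align_peaks(pr0$ref, pr0$lagged)
  expect_equal(ap0$follower_shift, 0, tolerance = 1e-9)
  prof <- ap0$profile
  expect_equal(prof$rel_time_s[which.max(prof$reference_mean)], 0)

  pr1 <- wave_pair(1, frame_interval = 0.5, noise_sd = 0, seed = 7)
  ap1 <- align_peaks(pr1$ref, pr1$lagged)
  expect_equal(ap1$follower_shift, 1, tolerance = 0.25)
})

test_that("peak alignment and cross-correlation agree within one frame", {
  pr <- wave_pair(0.8, frame_interval = 0.4, noise_sd = 0.08, seed = 9,
                  duration = 200)
  ap <- align_peaks(pr$ref, pr$lagged)
  ps <- xcorr_lag(pr$lagged, pr$ref, max_lag = 8, subsample = TRUE)
  expect_lt(abs(ap$follower_shift - ps$lag), 0.4)
})

test_that("too few reference peaks is an error", {
  t <- seq(0, 80, by = 1)
  one_peak <- tibble::tibble(time_s = t,
                             intensity = exp(-(t - 40)^2 / 20))
  expect_error(align_peaks(one_peak, one_peak),
               class = "curvesense_insufficient_peaks")
})

test_that("phase summaries report mean, SEM and n", {
  s1 <- summarize_phase(2.0)
  expect_equal(s1$mean_lag_s, 2.0)
  expect_true(is.na(s1$sem_lag_s))
  s3 <- summarize_phase(c(1.0, 1.0, 1.0))
  expect_equal(s3$mean_lag_s, 1.0)
  expect_equal(s3$sem_lag_s, 0)
  expect_error(summarize_phase(numeric(0)),
               class = "curvesense_invalid_parameters")

  lags <- vapply(1:50, function(seed) {
    pr <- wave_pair(2, frame_interval = 1, noise_sd = 0.1, seed = seed)
    xcorr_lag(pr$lagged, pr$ref, max_lag = 8, subsample = TRUE)$lag
  }, numeric(1))
  sm <- summarize_phase(lags)
  expect_lt(abs(sm$mean_lag_s - 2), 2 * sm$sem_lag_s + 1e-9)
})
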