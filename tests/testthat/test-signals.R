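test_that("uniform series validates inputs and exposes its time grid", {
  s <- uniform_series(1:5, rate = 50, t0 = 2)
  expect_equal(series_time(s), 2 + (0:4) / 50)
  expect_error(uniform_series(c(1, NA), 10), "finite")
  expect_error(uniform_series(1:3, -1), "rate")
})

test_that("recording round-trip through CSV preserves samples and rate", {
  tr <- generate_trial(gait_preset("healthy"), 8, seed = 11)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_recording(tr$imu, f1)
  write_recording(tr$fsw, f2)
  imu2 <- read_imu(f1, "right")
  fsw2 <- read_footswitch(f2, "right")
  expect_equal(imu2$rate, tr$imu$rate, tolerance = 1e-9)
  expect_equal(unname(imu2$gyro), unname(tr$imu$gyro), tolerance = 1e-9)
  expect_equal(unname(fsw2$channels), unname(tr$fsw$channels),
               tolerance = 1e-9)
})

test_that("readers infer the rate from timestamps and reject bad files", {
  f <- tempfile(fileext = ".csv")
  d <- data.frame(time = c(0, 0.02, 0.04), gx = 0, gy = 0, gz = 0,
                  ax = 0, ay = 0, az = 9.81)
  write.csv(d, f, row.names = FALSE)
  expect_equal(read_imu(f, "left")$rate, 50)
  d$time <- c(0, 0.02, 0.02)                # duplicated timestamp
  write.csv(d, f, row.names = FALSE)
  expect_error(read_imu(f, "left"), "increasing")
  d$time <- c(0, 0.02, 0.04); d$gz <- NULL  # missing channel
  write.csv(d, f, row.names = FALSE)
  expect_error(read_imu(f, "left"), "missing column")
})

test_that("resampling covers the span, interpolates, and holds binary values", {
  const <- uniform_series(rep(1, 50), 50)
  up <- resample_series(const, 200)
  expect_equal(up$rate, 200)
  expect_true(all(up$samples == 1))

  t <- seq(0, 2, by = 1 / 50)
  sine <- uniform_series(sin(2 * pi * t), 50)
  up <- resample_series(sine, 200)
  expect_lt(max(abs(up$samples - sin(2 * pi * series_time(up)))), 0.01)

  set.seed(1)
  bin <- uniform_series(rbinom(2000, 1, 0.3), 2000)
  held <- resample_series(bin, 200, mode = "hold")
  expect_true(all(held$samples %in% c(0, 1)))

  expect_error(resample_series(uniform_series(1, 10), 20), "2 samples")
})

test_that("resampling a band-limited series down and back is near-lossless", {
  t <- seq(0, 3, by = 1 / 200)
  x <- uniform_series(sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 7 * t), 200)
  back <- resample_series(resample_series(x, 400), 200)
  n <- min(length(back$samples), length(x$samples))
  rms <- sqrt(mean((back$samples[seq_len(n)] - x$samples[seq_len(n)])^2))
  expect_lt(rms, 0.01 * sqrt(mean(x$samples^2)))
})

test_that("Butterworth low-pass has unit DC gain and attenuates the stopband", {
  dc <- uniform_series(rep(2.5, 400), 200)
  expect_equal(apply_filter(dc, filter_spec("butterworth_lowpass", 2,
                                            cutoff_hz = 6))$samples,
               dc$samples, tolerance = 1e-6)
  t <- seq(0, 2, by = 1 / 200)
  hi <- uniform_series(sin(2 * pi * 30 * t), 200)
  out <- lowpass(hi, 6)
  mid <- 100:300
  atten_db <- 20 * log10(max(abs(out$samples[mid])))
  expect_lt(atten_db, -20)
  expect_error(lowpass(hi, 150), "Nyquist")
})

test_that("zero-phase filtering preserves the peak time of a symmetric pulse", {
  t <- seq(0, 2, by = 1 / 200)
  pulse <- uniform_series(exp(-(t - 1)^2 / (2 * 0.05^2)), 200)
  out <- lowpass(pulse, 10)
  expect_equal(which.max(out$samples), which.max(pulse$samples), tolerance = 1)
})

test_that("filters are linear operators", {
  set.seed(7)
  x <- uniform_series(rnorm(500), 200)
  y <- uniform_series(rnorm(500), 200)
  comb <- uniform_series(2 * x$samples - 3 * y$samples, 200)
  for (flt in list(function(s) lowpass(s, 8),
                   function(s) moving_average(s, 0.1))) {
    expect_equal(flt(comb)$samples,
                 2 * flt(x)$samples - 3 * flt(y)$samples, tolerance = 1e-9)
  }
})

test_that("moving average matches a direct convolution oracle", {
  set.seed(3)
  x <- rnorm(300)
  w <- 9                               # odd window: plain centered average
  got <- moving_average(uniform_series(x, 100), w / 100)$samples
  want <- vapply(seq_along(x), function(i) {
    lo <- max(1, i - 4); hi <- min(length(x), i + 4)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  const <- moving_average(uniform_series(rep(3.3, 50), 100), 0.05)
  expect_equal(const$samples, rep(3.3, 50), tolerance = 1e-12)

  imp <- moving_average(uniform_series(c(rep(0, 20), 1, rep(0, 20)), 100),
                        0.05)
  expect_equal(max(imp$samples), 1 / 5, tolerance = 1e-12)
})
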