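test_that("read_imu converts units and infers the rate from timestamps", {
  df <- data.frame(t = c(0, 0.005, 0.010, 0.015),
                   ax = 0, ay = 0, az = 1,      # 1 g
                   gx = 0, gy = 0, gz = c(0.1, 0.2, 0.3, 0.4) * pi / 180)
  path <- write_imu_fixture(df)
  seq <- read_imu(path, acc_unit = "g", gyr_unit = "rad/s")
  expect_equal(imu_rate(seq), 200)
  expect_equal(seq$az, rep(9.81, 4))
  expect_equal(seq$gz, c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
})

test_that("read_imu maps arbitrary column names and rejects missing ones", {
  df <- data.frame(time = c(0, 0.005, 0.010),
                   a1 = 1, a2 = 2, a3 = 3, g1 = 4, g2 = 5, g3 = 6)
  path <- write_imu_fixture(df)
  seq <- read_imu(path, column_map = c(t = "time", ax = "a1", ay = "a2",
                                       az = "a3", gx = "g1", gy = "g2",
                                       gz = "g3"))
  expect_equal(seq$gz, rep(6, 3))
  expect_error(read_imu(path, column_map = c(t = "time", ax = "a1")),
               class = "ipdr_format_error")
})

test_that("an isolated NaN is linearly interpolated from its neighbours", {
  df <- data.frame(t = (0:4) / 200, ax = 0, ay = 0, az = 9.81,
                   gx = 0, gy = 0, gz = c(1, 2, NaN, 4, 5))
  path <- write_imu_fixture(df)
  seq <- read_imu(path)
  expect_equal(seq$gz, c(1, 2, 3, 4, 5))  # hand interpolation: (2+4)/2
})

test_that("long NaN runs and non-monotone time are data errors", {
  n <- 100
  gz <- rep(1, n); gz[10:40] <- NaN   # 31 samples = 0.155 s at 200 Hz
  df <- data.frame(t = (0:(n - 1)) / 200, ax = 0, ay = 0, az = 9.81,
                   gx = 0, gy = 0, gz = gz)
  expect_error(read_imu(write_imu_fixture(df)), class = "ipdr_data_error")
  df2 <- data.frame(t = c(0, 0.01, 0.005), ax = 0, ay = 0, az = 9.81,
                    gx = 0, gy = 0, gz = 0)
  expect_error(read_imu(write_imu_fixture(df2)), class = "ipdr_data_error")
})

test_that("save-then-load round trip reproduces samples at 9 digits", {
  seq <- static_sequence(n = 50, gyr_sd = 10, acc_sd = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_imu(seq, path)
  back <- read_imu(path)
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
    expect_equal(back[[ch]], seq[[ch]], tolerance = 1e-8)
  }
})

test_that("resampling at the native rate is the identity", {
  seq <- static_sequence(n = 100, gyr_sd = 5, seed = 4)
  out <- resample_imu(seq, imu_rate(seq))
  expect_identical(out$gz, seq$gz)
})

test_that("non-uniform timestamps are resampled onto a uniform grid", {
  t <- c(0, 0.005, 0.0100, 0.0175, 0.020)   # one late sample
  df <- data.frame(t = t, ax = 0, ay = 0, az = 9.81,
                   gx = 0, gy = 0, gz = t * 100)
  seq <- read_imu(write_imu_fixture(df), rate_hz = 200)
  expect_equal(diff(seq$t), rep(0.005, nrow(seq) - 1), tolerance = 1e-12)
  expect_equal(seq$gz, seq$t * 100, tolerance = 1e-9)  # linear stays linear
})

test_that("gyro bias is the interval mean and gravity its accelerometer norm", {
  n <- 2000
  seq <- imu_sequence((0:(n - 1)) / 200,
                      matrix(rep(c(0, 0, 9.81), each = n), ncol = 3),
                      matrix(rep(c(0.5, -0.2, 0.1), each = n), ncol = 3))
  cal <- estimate_gyro_bias(seq)
  expect_equal(unname(cal$gyro_bias), c(0.5, -0.2, 0.1))
  expect_equal(cal$gravity_mag, 9.81)
})

test_that("white-noise bias estimate obeys the standard-error bound", {
  # sd 0.05 deg/s over 2000 samples: SE ~ 0.0011; 3 SE well under 0.01
  seq <- static_sequence(n = 2000, gyr_sd = 0.05, seed = 7)
  cal <- estimate_gyro_bias(seq, static_interval = c(1, 2000))
  expect_true(all(abs(cal$gyro_bias) < 0.01))
})

test_that("injected bias is recovered within 3 standard errors", {
  b <- c(0.5, -0.3, 0.8)
  seq <- static_sequence(n = 2000, gyr_sd = 0.05, bias = b, seed = 8)
  cal <- estimate_gyro_bias(seq)
  se <- 0.05 / sqrt(cal$static_interval["end"])
  expect_true(all(abs(cal$gyro_bias - b) < 3 * se))
})

test_that("calibration subtracts the bias and is idempotent to the noise floor", {
  seq <- static_sequence(n = 2000, gyr_sd = 0.02, bias = c(0.5, 0, 0), seed = 9)
  cal <- estimate_gyro_bias(seq)
  out <- apply_calibration(seq, cal)
  cal2 <- estimate_gyro_bias(out)
  expect_true(all(abs(cal2$gyro_bias) < 0.005))
  # residual angular-rate integral over 10 s stays below 0.05 deg
  expect_lt(abs(sum(out$gx) / 200), 0.05)
  # zero bias: identity
  zero <- cal; zero$gyro_bias <- c(x = 0, y = 0, z = 0)
  expect_identical(apply_calibration(out, zero)$gx, out$gx)
})

test_that("degenerate calibration intervals are rejected with named checks", {
  seq <- static_sequence(n = 500)
  expect_error(estimate_gyro_bias(seq, static_interval = c(1, 100)),
               "too short", class = "ipdr_calibration_error")
  noisy <- static_sequence(n = 1000, gyr_sd = 3, seed = 10)
  expect_error(estimate_gyro_bias(noisy, static_interval = c(1, 1000)),
               "too noisy", class = "ipdr_calibration_error")
  bad_g <- static_sequence(n = 1000)
  bad_g$az <- bad_g$az * 2
  expect_error(estimate_gyro_bias(bad_g, static_interval = c(1, 1000)),
               class = "ipdr_calibration_error")
})
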