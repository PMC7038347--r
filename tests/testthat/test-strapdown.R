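test_that("zero-velocity detection follows the gyro-magnitude and MS-window rules", {
  n <- 1000
  quiet <- imu_sequence((0:(n - 1)) / 200,
                        matrix(rep(c(0, 0, 9.81), each = n), ncol = 3),
                        matrix(0, n, 3), rate_hz = 200)
  expect_true(all(detect_zero_velocity(quiet, "walk")))
  loud <- quiet
  loud$gx <- rep(1, n)   # magnitude 1 deg/s >= 0.6
  expect_false(any(detect_zero_velocity(loud, "walk")))
  # jog: exactly MS +/- 5
  zv <- detect_zero_velocity(quiet, "jog", ms_indices = 500)
  expect_equal(which(zv), 495:505)
  expect_equal(attr(zv, "mode"), "ms_window")
  expect_error(detect_zero_velocity(quiet, "run"),
               class = "ipdr_precondition_error")
  # chatter shorter than 3 samples is dropped
  chat <- loud
  chat$gx[c(10, 11, 50, 51, 52)] <- 0
  expect_equal(which(detect_zero_velocity(chat, "walk")), 50:52)
})

test_that("stationary noise-free input stays put", {
  seq <- static_sequence(n = 2000)
  nav <- strapdown_integrate(seq)
  n <- nrow(nav)
  expect_lt(sqrt(nav$px[n]^2 + nav$py[n]^2 + nav$pz[n]^2), 1e-6)
})

test_that("constant acceleration integrates to the closed form within 1%", {
  n <- 401   # 2 s at 200 Hz
  acc <- matrix(rep(c(1, 0, 9.81), each = n), ncol = 3)
  seq <- imu_sequence((0:(n - 1)) / 200, acc, matrix(0, n, 3), rate_hz = 200)
  nav <- strapdown_integrate(seq, initial = list(C0 = diag(3), v0 = c(0, 0, 0),
                                                 p0 = c(0, 0, 0)))
  expect_equal(nav$px[n], 2, tolerance = 0.01)   # 0.5 * 1 * 2^2
  expect_lt(abs(nav$py[n]), 1e-9)
})

test_that("a pure 90 deg/s rotation for 1 s turns the heading by 90 degrees", {
  n <- 201
  # specific force follows the rotating body so velocity stays zero
  t <- (0:(n - 1)) / 200
  acc <- t(vapply(t, function(tt) {
    as.numeric(t(ipdr:::rot_z(pi / 2 * tt)) %*% c(0, 0, 9.81))
  }, numeric(3)))
  gyr <- matrix(rep(c(0, 0, 90), each = n), ncol = 3)
  seq <- imu_sequence(t, acc, gyr, rate_hz = 200)
  nav <- strapdown_integrate(seq, initial = list(C0 = diag(3), v0 = c(0, 0, 0),
                                                 p0 = c(0, 0, 0)))
  expect_equal(nav$yaw[n] * 180 / pi, 90, tolerance = 0.01)
})

test_that("rotation matrices stay orthonormal along the whole path", {
  gt <- plan_trajectory(gait_plan("run", n_strides = 6))
  seq <- synthesize_imu(gt, noise_model(0.05, 0.2, seed = 61))
  nav <- zupt_kalman(seq, gt$samples$zv)
  C <- attr(nav, "C")
  for (k in seq(1, dim(C)[3], by = 97)) {
    expect_lt(max(abs(crossprod(C[, , k]) - diag(3))), 1e-9)
  }
})

test_that("with no zero-velocity samples the filter equals pure strapdown", {
  seq <- static_sequence(n = 500, gyr_sd = 0.1, acc_sd = 0.05, seed = 62)
  a <- strapdown_integrate(seq)
  b <- zupt_kalman(seq, rep(FALSE, 500))
  expect_identical(a$px, b$px)
  expect_identical(a$vz, b$vz)
})

test_that("all-true ZUPT on stationary noise bounds velocity and position", {
  seq <- static_sequence(n = 2000, gyr_sd = 0.2, acc_sd = 0.05, seed = 63)
  zv <- rep(TRUE, 2000)
  nav <- zupt_kalman(seq, zv)
  free <- strapdown_integrate(seq)
  n <- 2000
  speed <- sqrt(nav$vx^2 + nav$vy^2 + nav$vz^2)
  expect_lt(stats::median(speed[-(1:10)]), 0.05)
  drift_zupt <- sqrt(nav$px[n]^2 + nav$py[n]^2 + nav$pz[n]^2)
  drift_free <- sqrt(free$px[n]^2 + free$py[n]^2 + free$pz[n]^2)
  expect_lt(drift_zupt, drift_free / 10)
})

test_that("the covariance trace never increases across a measurement update", {
  gt <- plan_trajectory(gait_plan("walk", n_strides = 6, lead_in_s = 2))
  seq <- synthesize_imu(gt, noise_model(0.05, 0.2, seed = 64))
  nav <- zupt_kalman(seq, gt$samples$zv)
  tr <- attr(nav, "cov_trace")
  expect_gt(nrow(tr), 100)
  expect_true(all(tr$after <= tr$before + 1e-15))
})

test_that("ZUPT beats pure strapdown on noisy closed loops (median over seeds)", {
  rpes <- vapply(1:5, function(s) {
    gt <- plan_trajectory(closed_loop_plan("walk", strides_per_side = 5,
                                           lead_in_s = 4))
    seq <- synthesize_imu(gt, noise_model(0.05, 0.2, gyr_bias = c(0.5, 0.5, 0.5),
                                          seed = 70 + s))
    cal <- estimate_gyro_bias(seq)
    seq <- apply_calibration(seq, cal)
    zv <- detect_zero_velocity(seq, "walk")
    n <- nrow(seq)
    nav <- zupt_kalman(seq, zv)
    free <- strapdown_integrate(seq)
    c(sqrt(nav$px[n]^2 + nav$py[n]^2), sqrt(free$px[n]^2 + free$py[n]^2))
  }, numeric(2))
  expect_lt(stats::median(rpes[1, ]), stats::median(rpes[2, ]) / 10)
})

test_that("the sigma_v sweep returns the grid minimizer", {
  gt <- plan_trajectory(closed_loop_plan("walk", strides_per_side = 4,
                                         lead_in_s = 2))
  seq <- synthesize_imu(gt, noise_model(0.05, 0.2, seed = 65))
  zv <- detect_zero_velocity(seq, "walk")
  grid <- seq(0.002, 0.02, by = 0.002)
  sw <- sweep_sigma_v(seq, zv, c(0, 0), grid = grid)
  expect_equal(sw$table$sigma_v, grid)
  expect_equal(min(sw$table$rpe_m),
               sw$table$rpe_m[sw$table$sigma_v == sw$sigma_v])
  # a one-point grid returns that point
  one <- sweep_sigma_v(seq, zv, c(0, 0), grid = 0.01)
  expect_equal(one$sigma_v, 0.01)
})

test_that("non-finite samples abort integration", {
  seq <- static_sequence(n = 100)
  seq$ax[50] <- NaN
  expect_error(strapdown_integrate(seq), class = "ipdr_numeric_error")
})
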