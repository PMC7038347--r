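test_that("stride length is the planar norm of the increment", {
  expect_equal(stride_length(c(0, 0, 0), c(3, 4, 7)), 5)
  expect_equal(stride_length(c(0, 0), c(0, 0)), 0)
  expect_equal(stride_length(c(1, 1, 0), c(1, 1, 5)), 0)  # vertical ignored
})

test_that("total distance equals the sum of stride lengths to 1e-12", {
  nav <- tibble::tibble(px = c(0, 1, 2, 2, 2), py = c(0, 0, 0, 3, 6))
  traj <- stride_trajectory(nav, ms_indices = 2:5)
  expect_equal(traj$sl, c(1, 1, 3, 3))
  expect_equal(attr(traj, "total_distance"), sum(traj$sl), tolerance = 1e-12)
  expect_equal(traj$heading_deg, c(0, 0, 90, 90))
})

test_that("event scoring applies the 15% tolerance rule exactly", {
  bounds <- tibble::tibble(start = 1, end = 200)
  hit <- score_events(129, 100, bounds)           # |29| <= 30
  expect_equal(hit$tp, 1L)
  expect_equal(hit$f_score, 1)
  miss <- score_events(131, 100, bounds)          # |31| > 30
  expect_equal(miss$tp, 0L)
  expect_equal(miss$fp, 1L)
  expect_equal(miss$fn, 1L)
  expect_equal(miss$f_score, 0)
  none <- score_events(integer(0), 100, bounds)
  expect_equal(none$fn, 1L)
  expect_equal(none$f_score, 0)
})

test_that("event matching is one-to-one, greedy nearest-first", {
  bounds <- tibble::tibble(start = c(1, 201), end = c(200, 400))
  # two truths, three detections; the two nearest pair up, one FP remains
  sc <- score_events(c(101, 105, 290), c(100, 300), bounds)
  expect_equal(sc$tp, 2L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 0L)
  expect_error(score_events(1, c(10, 20),
                            tibble::tibble(start = c(1, 50), end = c(60, 100))),
               class = "ipdr_input_error")
})

test_that("the F-score is non-decreasing in the tolerance fraction", {
  withr::with_seed(71, {
    bounds <- tibble::tibble(start = seq(1, 1801, by = 200),
                             end = seq(200, 2000, by = 200))
    truth <- round((bounds$start + bounds$end) / 2)
    detected <- truth + sample(-60:60, 10, replace = TRUE)
    fs <- vapply(seq(0.05, 0.3, by = 0.05), function(tol) {
      score_events(detected, truth, bounds, tolerance = tol)$f_score
    }, numeric(1))
    expect_true(all(diff(fs) >= 0))
  })
})

test_that("return position error reports metres and percent of distance", {
  nav <- tibble::tibble(px = c(0, 50, 100, 150, 1), py = c(0, 0, 0, 0, 0))
  traj <- stride_trajectory(nav, 2:5)
  rpe <- return_position_error(traj, c(0, 0))
  expect_equal(rpe$rpe_m, 1)
  expect_equal(rpe$rpe_pct, 100 * 1 / (50 + 50 + 50 + 149))
  exact <- return_position_error(traj, c(1, 0))
  expect_equal(exact$rpe_m, 0)
})

test_that("return position error is invariant to a rigid rotation", {
  withr::with_seed(72, {
    pts <- cbind(cumsum(stats::runif(8)), cumsum(stats::rnorm(8)))
    nav <- tibble::tibble(px = pts[, 1], py = pts[, 2])
    traj <- stride_trajectory(nav, 1:8)
    end <- c(3, 1)
    r0 <- return_position_error(traj, end)
    th <- 0.83
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- pts %*% t(R)
    trajr <- stride_trajectory(tibble::tibble(px = rot[, 1], py = rot[, 2]), 1:8)
    rr <- return_position_error(trajr, as.numeric(R %*% end))
    expect_equal(rr$rpe_m, r0$rpe_m, tolerance = 1e-9)
  })
})

test_that("strides out of trajectory uses boundary-inclusive point-in-polygon", {
  square <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  nav <- tibble::tibble(px = c(0.5, 1.0, 2, 0.2, -1, 0.9, 3, 0.1, 0.5, 5),
                        py = c(0.5, 0.5, 2, 0.2, -1, 0.1, 0, 0.9, 1.0, 5))
  traj <- stride_trajectory(nav, 1:10)
  sot <- strides_out_of_trajectory(traj, list(square))
  # points 3, 5, 7, 10 are outside; 2 and 9 are on the boundary -> inside
  expect_equal(sot$sot_count, 4L)
  expect_equal(sot$sot_pct, 40)
  bowtie <- data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(strides_out_of_trajectory(traj, list(bowtie)),
               class = "ipdr_input_error")
})

test_that("a union of zones covers disjoint corridors", {
  z1 <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  z2 <- data.frame(x = c(5, 6, 6, 5), y = c(0, 0, 1, 1))
  nav <- tibble::tibble(px = c(0.5, 5.5, 3), py = c(0.5, 0.5, 0.5))
  traj <- stride_trajectory(nav, 1:3)
  sot <- strides_out_of_trajectory(traj, list(z1, z2))
  expect_equal(sot$sot_count, 1L)
})

test_that("mean estimated stride length tracks the plan within 2%", {
  gt <- plan_trajectory(gait_plan("walk", n_strides = 12, stride_length_m = 1,
                                  lead_in_s = 4))
  seq <- synthesize_imu(gt, noise_model(0.05, 0.2, seed = 73))
  zv <- detect_zero_velocity(seq, "walk")
  nav <- zupt_kalman(seq, zv)
  traj <- stride_trajectory(nav, gt$events$ms)
  expect_equal(mean(traj$sl), 1, tolerance = 0.02)
})
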