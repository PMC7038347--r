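test_that("toe-off is the zero-crossing nearest the swing peak", {
  expect_equal(as.integer(detect_toe_off(c(-1, -0.5, 0.2, 1, 3, 1, -1))), 3L)
})

test_that("toe-off anchors on the global maximum, not an early blip", {
  # spurious positive blip, dip, then the true swing peak
  stride <- c(-2, 0.5, 1, -1, -2, -0.5, 0.4, 2, 6, 3, -1, -2)
  expect_equal(as.integer(detect_toe_off(stride)), 7L)
  # a first-crossing rule would have said 2
  expect_false(attr(detect_toe_off(stride), "low_confidence"))
})

test_that("toe-off is invariant to positive rescaling", {
  withr::with_seed(41, {
    for (i in 1:10) {
      stride <- rnorm(80)
      if (all(stride <= 0)) stride[40] <- 1
      expect_equal(as.integer(detect_toe_off(stride)),
                   as.integer(detect_toe_off(stride * 7.3)))
    }
  })
})

test_that("strides without a swing peak or crossing degrade explicitly", {
  expect_error(detect_toe_off(c(-1, -2, -0.5)), class = "ipdr_event_error")
  no_crossing <- c(3, 2, 1, 0.5, 0.2, 0.1)   # positive from the start
  out <- detect_toe_off(no_crossing)
  expect_equal(as.integer(out), 1L)
  expect_true(attr(out, "low_confidence"))
})

test_that("mid-stance lands in a zero plateau; ties go to the earlier window", {
  # 200-sample stride: peak at 50, descent to a minimum at 110, exact zero
  # plateau 120..160
  y <- numeric(200)
  y[1:49] <- -1
  y[50] <- 10
  y[51:109] <- seq(5, -4, length.out = 59)
  y[110] <- -6
  y[111:119] <- seq(-3, -0.5, length.out = 9)
  y[161:200] <- -1
  ms <- detect_mid_stance(y)
  hs <- attr(ms, "hs_idx")
  expect_equal(hs, 110L)
  # windows of 20 slide from HS by 10: [110,129] touches the descent,
  # [120,139] is the earliest all-zero window; [130,149] ties but is later.
  # centre of [120,139] is 129.5, mapped to sample 130
  expect_equal(as.integer(ms), 130L)
  expect_error(detect_mid_stance(y[1:30]), class = "ipdr_event_error")
})

test_that("mid-stance sits after heel strike and before 80% of the stride", {
  withr::with_seed(42, {
    for (a in c("walk", "jog", "run")) {
      gt <- plan_trajectory(gait_plan(a, n_strides = 6, jitter = 0.05),
                            seed = 43)
      seq <- synthesize_imu(gt, noise_model(0, 1, seed = 44))
      for (i in seq_len(nrow(gt$events))) {
        s <- gt$events$start[i]; e <- gt$events$end[i]
        x <- seq$gz[s:e]
        ms <- detect_mid_stance(x)
        expect_gte(as.integer(ms), attr(ms, "hs_idx"))
        expect_lte(as.integer(ms), ceiling(0.8 * length(x)) + 1)
      }
    }
  })
})

test_that("restitching spans consecutive toe-offs and truncates long spans", {
  # synthetic signal with swing peaks so TOs land at 100 and 300
  sig <- rep(-0.1, 800)
  bump <- function(at) {
    i <- at:(at + 40)
    sin(pi * (i - at) / 40) * 5
  }
  sig[100:140] <- bump(100)
  sig[300:340] <- bump(300)
  segments <- tibble::tibble(start = c(60, 260), end = c(240, 440))
  st <- restitch_to_to(segments, sig, rate_hz = 200)
  # the crossing rule x[i-1] <= 0 < x[i] puts TO on the first positive sample
  expect_equal(st$to[1:2], c(101L, 301L))
  expect_equal(st$start[1], 101L)
  expect_equal(st$end[1], 300L)
  # spans > 2 s keep only their first 1.5 s
  sig2 <- rep(-0.1, 1200)
  sig2[100:140] <- bump(100)
  sig2[700:740] <- bump(700)   # 3 s apart at 200 Hz
  st2 <- restitch_to_to(tibble::tibble(start = c(60, 660), end = c(240, 840)),
                        sig2, rate_hz = 200)
  expect_equal(st2$start[1], 101L)
  expect_equal(st2$end[1], 101L + 300L - 1L)
})

test_that("restitched strides tile a synthetic bout without gaps", {
  tpl <- default_templates()$walk
  gt <- plan_trajectory(gait_plan("walk", n_strides = 10))
  seq <- synthesize_imu(gt, noise_model(0.02, 0.5, seed = 45))
  seg <- subsequence_dtw(seq$gz, tpl, default_msdtw_threshold)
  st <- restitch_to_to(seg, seq$gz, imu_rate(seq))
  expect_gte(nrow(st), 9)
  expect_true(all(st$start[-1] == utils::head(st$end, -1) + 1L))
})

test_that("detected events keep the stride ordering invariant", {
  gt <- plan_trajectory(gait_plan("run", n_strides = 8))
  seq <- synthesize_imu(gt, noise_model(0.02, 1, seed = 46))
  ev <- detect_events(gt$events[, c("start", "end")], seq$gz)
  expect_equal(nrow(ev), 8L)
  expect_true(all(ev$start <= ev$to & ev$to < ev$ms & ev$ms <= ev$end))
})
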