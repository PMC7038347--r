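# shared in-code fixtures

static_sequence <- function(n = 1000, rate = 200, bias = c(0, 0, 0),
                            gyr_sd = 0, acc_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    gyr <- matrix(rnorm(3 * n, sd = gyr_sd), n, 3)
    acc <- matrix(rnorm(3 * n, sd = acc_sd), n, 3)
  })
  gyr <- sweep(gyr, 2, bias, "+")
  acc[, 3] <- acc[, 3] + 9.81
  imu_sequence((seq_len(n) - 1) / rate, acc, gyr, rate_hz = rate)
}

write_imu_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "NaN")
  path
}
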