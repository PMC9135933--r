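test_that("averaging identical noise-free beats reproduces the template", {
  sim <- simulate_ecg(ecg_params("nmr", resp_depth = 0, rr_jitter = 0),
                      duration_s = 40, seed = 2)
  rr <- rr_series(sim$truth$r_times)
  avg <- average_beats(sim$recording, rr, n = 100)
  expect_equal(avg$n_averaged, 100)
  # compare against an analytically rendered template on the same axis
  p <- ecg_params("nmr", resp_depth = 0, rr_jitter = 0)
  tpl <- p$lead_weights["L1", "P"] * cardiochron:::render_waves(avg$time_ms, p$waves, "P") +
    p$lead_weights["L1", "QRS"] * cardiochron:::render_waves(avg$time_ms, p$waves, c("Q", "R", "S")) +
    p$lead_weights["L1", "T"] * cardiochron:::render_waves(avg$time_ms, p$waves, "T")
  # sub-sample alignment jitter bounds the residual
  expect_lt(sqrt(mean((avg$mean[, "L1"] - tpl)^2)), 0.01)
})

test_that("residual noise after averaging follows the 1/sqrt(n) law", {
  rms <- sapply(c(25, 100), function(n) {
    noisy <- simulate_ecg(ecg_params("mouse"), duration_s = 60,
                          noise_sd = 0.10, seed = 4)
    clean <- simulate_ecg(ecg_params("mouse"), duration_s = 60,
                          noise_sd = 0, seed = 4)
    rr <- rr_series(noisy$truth$r_times)
    a_n <- average_beats(noisy$recording, rr, n = n)
    a_c <- average_beats(clean$recording, rr, n = n)
    sqrt(mean((a_n$mean[, "L1"] - a_c$mean[, "L1"])^2))
  })
  expect_equal(rms[1], 0.10 / sqrt(25), tolerance = 0.20)
  expect_equal(rms[2], 0.10 / sqrt(100), tolerance = 0.20)
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.20)
})

test_that("requesting more beats than available records the actual count", {
  sim <- simulate_ecg(ecg_params("nmr"), duration_s = 14, seed = 3)
  rr <- rr_series(sim$truth$r_times)
  avg <- average_beats(sim$recording, rr, n = 100)
  expect_lt(avg$n_averaged, 100)
  expect_gte(avg$n_averaged, 20)
})

test_that("fewer than 20 usable beats is rejected with the count", {
  sim <- simulate_ecg(ecg_params("nmr"), duration_s = 4, seed = 3)
  rr <- rr_series(sim$truth$r_times)
  expect_error(average_beats(sim$recording, rr, n = 100), "usable beats")
})

test_that("suspect beats are excluded from the template", {
  arr <- arrhythmia_spec(p_vpb = 0.03)
  sim <- simulate_ecg(ecg_params("mouse"), arr, duration_s = 60, seed = 6)
  rr <- rr_series(sim$truth$r_times)
  flags <- flag_irregular(rr)
  avg <- average_beats(sim$recording, rr, flags, n = 100)
  # a template contaminated by 2.5x-wide VPBs would widen at half height;
  # compare widths against the clean-template expectation
  y <- avg$mean[, "L1"]
  w50 <- sum(y > 0.5 * max(y)) / avg$fs * 1000
  p <- ecg_params("mouse")
  tpl <- cardiochron:::render_waves(avg$time_ms, p$waves, c("Q", "R", "S"))
  w50_tpl <- sum(tpl > 0.5 * max(tpl)) / avg$fs * 1000
  expect_lt(abs(w50 - w50_tpl), 0.6)
})
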