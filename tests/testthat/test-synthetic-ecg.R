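test_that("event-free simulation yields the expected beat count, all normal", {
  sim <- simulate_ecg(ecg_params("mouse"), duration_s = 300, seed = 1)
  n <- length(sim$truth$r_times)
  expect_gte(n, 2500)
  expect_lte(n, 3000)
  expect_true(all(sim$truth$labels == "normal"))
})

test_that("equal seeds give bit-identical recordings; noise stream is separate", {
  p <- ecg_params("nmr")
  a <- simulate_ecg(p, duration_s = 20, noise_sd = 0.02, seed = 7)
  b <- simulate_ecg(p, duration_s = 20, noise_sd = 0.02, seed = 7)
  expect_identical(a, b)
  # different noise level must not perturb beat placement (substreams)
  c2 <- simulate_ecg(p, duration_s = 20, noise_sd = 0.1, seed = 7)
  expect_identical(a$truth$r_times, c2$truth$r_times)
  expect_identical(a$truth$labels, c2$truth$labels)
})

test_that("injected APB fraction is binomially calibrated and premature", {
  p_ev <- 0.02
  sim <- simulate_ecg(ecg_params("mouse"), arrhythmia_spec(p_apb = p_ev),
                      duration_s = 300, seed = 3)
  lab <- sim$truth$labels
  n <- length(lab)
  expect_gte(n, 1000)
  n_apb <- sum(lab == "APB")
  ci <- qbinom(c(0.005, 0.995), n, p_ev)
  expect_gte(n_apb, ci[1])
  expect_lte(n_apb, ci[2])
  # every APB's preceding R-R below 0.7 * mean RR
  ap <- which(lab == "APB")
  coupling <- (sim$truth$r_times[ap] - sim$truth$r_times[ap - 1]) * 1000
  expect_lt(max(coupling), 0.7 * sim$truth$rr_mean_ms)
})

test_that("beat morphology matches labels: VPB wide, APB keeps P, JPB lacks it", {
  p <- ecg_params("mouse")
  arr <- arrhythmia_spec(p_apb = 0.02, p_vpb = 0.02, p_jpb = 0.02)
  sim <- simulate_ecg(p, arr, duration_s = 120, seed = 9)
  rec <- sim$recording; tr <- sim$truth
  fs <- rec$fs
  ti <- ecg_true_intervals(p)
  # P-wave sample: value at the true P peak offset, L1, baseline-corrected
  p_val <- function(b) {
    i <- round((tr$r_times[b] + ti$p_peak_ms / 1000) * fs) + 1
    rec$signal[i, "L1"]
  }
  for (cls in c("APB", "VPB", "JPB")) {
    beats <- which(tr$labels == cls)
    expect_gt(length(beats), 0)
    if (cls == "APB") {
      expect_true(all(vapply(beats, p_val, numeric(1)) > 0.05))
    }
  }
  # VPB rendered QRS width: half-width of the R wave at 50% amplitude
  halfwidth <- function(b) {
    ctr <- round(tr$r_times[b] * fs) + 1
    w <- rec$signal[(ctr - 60):(ctr + 60), "L1"]
    sum(w > 0.5 * max(w)) / fs * 1000
  }
  hw_norm <- median(vapply(which(tr$labels == "normal")[1:50], halfwidth,
                           numeric(1)))
  hw_vpb <- vapply(which(tr$labels == "VPB"), halfwidth, numeric(1))
  expect_true(all(hw_vpb >= 2.5 * 0.8 * hw_norm))
})

test_that("compensatory and resetting pause conventions hold", {
  p <- ecg_params("nmr")
  rrm <- 60000 / p$hr_mean
  sim_v <- simulate_ecg(p, arrhythmia_spec(p_vpb = 0.02), 120, seed = 5)
  vb <- which(sim_v$truth$labels == "VPB")
  t <- sim_v$truth$r_times
  pre <- (t[vb] - t[vb - 1]) * 1000
  post <- (t[vb + 1] - t[vb]) * 1000
  expect_equal(pre + post, rep(2 * rrm, length(vb)), tolerance = 1e-6)
  sim_j <- simulate_ecg(p, arrhythmia_spec(p_jpb = 0.02), 120, seed = 5)
  jb <- which(sim_j$truth$labels == "JPB")
  t <- sim_j$truth$r_times
  post <- (t[jb + 1] - t[jb]) * 1000
  expect_equal(post, rep(rrm, length(jb)), tolerance = 1e-6)
})

test_that("invalid simulation inputs are rejected", {
  p <- ecg_params("mouse")
  expect_error(simulate_ecg(p, duration_s = -1, seed = 1), "duration")
  expect_error(simulate_ecg(p, duration_s = 10, fs = 400, seed = 1),
               "sampling rate")
  expect_error(simulate_ecg(p, duration_s = 10), "seed")
  expect_error(arrhythmia_spec(p_apb = 0.15, p_vpb = 0.1), "0.2")
  expect_error(arrhythmia_spec(prematurity = c(0.2, 0.9)), "prematurity")
  expect_error(ecg_params("mouse", hr_mean = -5), "hr_mean")
})

test_that("qrs_ms and pq_ms targets reshape the template ground truth", {
  for (q in c(7, 12)) {
    p <- ecg_params("mouse", qrs_ms = q)
    expect_equal(ecg_true_intervals(p)$qrs_ms, q, tolerance = 1e-9)
  }
  p <- ecg_params("nmr", pq_ms = 40)
  expect_equal(ecg_true_intervals(p)$pq_ms, 40, tolerance = 1e-9)
})
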