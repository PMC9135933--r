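measure_on_sim <- function(sp, qrs = NULL, snr = Inf, seed = 2,
                           duration = 45) {
  p <- ecg_params(sp, qrs_ms = qrs)
  ns <- if (is.finite(snr)) ecg_noise_sd(p, snr) else 0
  sim <- simulate_ecg(p, duration_s = duration, noise_sd = ns, seed = seed)
  rr <- rr_series(detect_r_peaks(sim$recording))
  flags <- flag_irregular(rr)
  avg <- average_beats(sim$recording, rr, flags, n = 100)
  list(fid = measure_intervals(avg), truth = sim$truth$intervals)
}

test_that("noise-free QRS is recovered within 1 ms, PQ and PR within 2 ms", {
  for (q in c(6, 10, 14)) {
    r <- measure_on_sim("mouse", qrs = q)
    expect_lt(abs(r$fid$qrs_ms - r$truth$qrs_ms), 1, label = paste("mouse QRS", q))
    expect_lt(abs(r$fid$pq_ms - r$truth$pq_ms), 2)
    expect_lt(abs(r$fid$pr_ms - r$truth$pr_ms), 2)
  }
  for (q in c(8, 14, 20)) {
    r <- measure_on_sim("nmr", qrs = q)
    expect_lt(abs(r$fid$qrs_ms - r$truth$qrs_ms), 1, label = paste("nmr QRS", q))
    expect_lt(abs(r$fid$pq_ms - r$truth$pq_ms), 2)
    expect_lt(abs(r$fid$pr_ms - r$truth$pr_ms), 2)
  }
})

test_that("fiducial ordering invariants hold on measured beats", {
  r <- measure_on_sim("nmr")
  f <- r$fid
  expect_lt(f$p_onset_ms, f$p_peak_ms)
  expect_lt(f$p_peak_ms, f$qrs_onset_ms)
  expect_lt(f$qrs_onset_ms, 0)
  expect_gt(f$qrs_offset_ms, 0)
  expect_gt(f$qrs_ms, 0); expect_gt(f$pr_ms, 0); expect_gt(f$pq_ms, 0)
})

test_that("a flat averaged beat is rejected", {
  avg <- structure(
    list(time_ms = seq(-50, 60, by = 0.5),
         mean = matrix(0, 221, 1, dimnames = list(NULL, "L1")),
         sd = matrix(0, 221, 1), n_averaged = 100,
         median_rr_ms = 110, fs = 2000),
    class = "averaged_beat")
  expect_error(measure_intervals(avg), "flat")
})

test_that("absent P wave reports missing PR/PQ but still returns QRS", {
  # render a P-less template directly (junctional-like morphology)
  p <- ecg_params("mouse")
  t_ms <- seq(-49, 60, by = 0.5)
  y <- cardiochron:::render_waves(t_ms, p$waves, c("Q", "R", "S", "T"))
  avg <- structure(
    list(time_ms = t_ms, mean = matrix(y, dimnames = list(NULL, "L1")),
         sd = matrix(0, length(y), 1), n_averaged = 100,
         median_rr_ms = 109, fs = 2000),
    class = "averaged_beat")
  f <- measure_intervals(avg)
  expect_true(is.na(f$pr_ms))
  expect_true(is.na(f$pq_ms))
  expect_equal(f$qrs_ms, ecg_true_intervals(p)$qrs_ms, tolerance = 1)
})
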