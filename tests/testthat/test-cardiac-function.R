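test_that("function metrics satisfy their defining identities", {
  m <- function_metrics(edv = 60, esv = 30, hr = 600, body_weight = 30)
  expect_equal(m$sv_ul, 30)
  expect_equal(m$ef_pct, 50)
  expect_equal(m$co_ml_min, 18)
  expect_equal(m$nco_ml_min_g, 0.6)
  # boundaries
  expect_equal(function_metrics(60, 0, 600, 30)$ef_pct, 100)
  z <- function_metrics(60, 60, 600, 30)
  expect_equal(z$ef_pct, 0); expect_equal(z$sv_ul, 0)
  # identity re-derivable from outputs
  expect_equal(m$edv_ul, m$sv_ul * 100 / m$ef_pct)
})

test_that("implausible volume inputs are rejected", {
  expect_error(function_metrics(60, 70, 600, 30), "segmentation")
  expect_error(function_metrics(-5, 0, 600, 30), "edv")
  expect_error(function_metrics(60, 30, 0, 30), "hr")
  expect_error(function_metrics(60, 30, 600, 0), "body_weight")
})

test_that("biplane volume is exact for sphere and ellipsoid", {
  expect_equal(biplane_la_volume(pi, pi, 2), 4 * pi / 3, tolerance = 1e-12)
  # semi-axes (1, 2, 3): views pi*1*3 and pi*2*3, length 6
  expect_equal(biplane_la_volume(3 * pi, 6 * pi, 6), 8 * pi,
               tolerance = 1e-12)
  expect_error(biplane_la_volume(3, 3, 0), "long_axis")
})

test_that("biplane volume scales as k^3 under isotropic scaling", {
  set.seed(31)
  for (i in 1:20) {
    a2 <- runif(1, 1, 30); a4 <- runif(1, 1, 30); L <- runif(1, 1, 10)
    k <- runif(1, 0.3, 4)
    expect_equal(biplane_la_volume(a2 * k^2, a4 * k^2, L * k),
                 k^3 * biplane_la_volume(a2, a4, L), tolerance = 1e-12)
  }
})

test_that("stress deltas reproduce printed percent changes", {
  b <- function_metrics(60, 30, 234, 40)
  s <- function_metrics(60, 25, 270, 40)
  d <- stress_delta(b, s)
  expect_equal(d$delta_pct[["hr_bpm"]], 100 * (270 - 234) / 234,
               tolerance = 1e-12)  # +15.4%
  expect_equal(round(d$delta_pct[["hr_bpm"]], 1), 15.4)
  # identity and simple arithmetic cases
  expect_true(all(stress_delta(b, b)$delta_pct == 0))
  b2 <- function_metrics(60, 30, 600, 30)
  s2 <- function_metrics(57, 30, 600, 30)
  expect_equal(stress_delta(b2, s2)$delta_pct[["sv_ul"]], -10)
})

test_that("forward and reverse deltas are multiplicative inverses", {
  b <- function_metrics(55, 22, 520, 28)
  s <- function_metrics(62, 18, 590, 28)
  d1 <- stress_delta(b, s)$delta_pct
  d2 <- stress_delta(s, b)$delta_pct
  for (m in names(d1)) {
    expect_equal((1 + d1[[m]] / 100) * (1 + d2[[m]] / 100), 1,
                 tolerance = 1e-12)
  }
})

test_that("E/A analysis recovers configured ratios and flags fusion", {
  r <- ea_analysis(simulate_doppler(600, 300, hr = 240, duration_s = 4,
                                    seed = 1))
  expect_true(r$separable)
  expect_equal(r$ea_ratio, 2.00, tolerance = 0.02)
  # equal peaks
  r1 <- ea_analysis(simulate_doppler(500, 500, hr = 240, duration_s = 4,
                                     seed = 3))
  expect_equal(r1$ea_ratio, 1.0, tolerance = 0.02)
  # fused at high heart rate: no ratio ever
  rf <- ea_analysis(simulate_doppler(600, 300, hr = 650, duration_s = 4,
                                     seed = 2))
  expect_false(rf$separable)
  expect_true(is.na(rf$ea_ratio))
  expect_error(ea_analysis(data.frame(time_s = 1:10 / 100,
                                      velocity_mm_s = rep(0, 10))),
               "all-zero")
})
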