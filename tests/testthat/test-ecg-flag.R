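test_that("a single short interval on a constant background flags once at 0.60", {
  rr <- rr_series(cumsum(c(0, rep(0.25, 10), 0.15, rep(0.25, 10))) )
  f <- flag_irregular(rr)
  expect_equal(sum(f$suspect), 1)
  expect_equal(f$rr_ratio[f$suspect], 0.60, tolerance = 1e-12)
  expect_equal(f$interval[f$suspect], 11L)
  expect_equal(f$beat[f$suspect], 12L)  # the beat terminating the interval
})

test_that("constant R-R series produces no flags", {
  f <- flag_irregular(rr_series(seq(0, 5, by = 0.25)))
  expect_false(any(f$suspect))
  expect_true(all(f$rr_ratio == 1))
})

test_that("flags match a brute-force oracle on seeded random-walk series", {
  set.seed(101)
  for (k in 1:50) {
    n <- sample(50:400, 1)
    rr_ms <- pmax(50, 250 * cumprod(1 + rnorm(n, 0, 0.08)))
    rr <- rr_series(cumsum(c(0, rr_ms)) / 1000)
    got <- flag_irregular(rr)$suspect
    want <- brute_force_flags(rr$rr_ms)
    expect_identical(got, want)
  }
})

test_that("flagging is invariant under rescaling of all intervals", {
  set.seed(7)
  rr_ms <- pmax(60, 250 * cumprod(1 + rnorm(200, 0, 0.1)))
  f1 <- flag_irregular(rr_series(cumsum(c(0, rr_ms)) / 1000))$suspect
  f2 <- flag_irregular(rr_series(cumsum(c(0, 3.7 * rr_ms)) / 1000))$suspect
  expect_identical(f1, f2)
})

test_that("consecutive suspect intervals sharing a beat merge into one event", {
  # a premature beat creates one short and one long interval back to back
  rr <- rr_series(cumsum(c(0, rep(0.25, 8), 0.12, 0.38, rep(0.25, 8))))
  f <- flag_irregular(rr)
  expect_equal(sum(f$suspect), 2)
  expect_equal(n_events(f), 1L)
})

test_that("threshold validation and minimum length are enforced", {
  rr <- rr_series(c(0, 0.25, 0.5, 0.75, 1.0))
  expect_error(flag_irregular(rr, low = 1.4, high = 1.3), "low")
  expect_error(flag_irregular(rr, low = 0), "low")
  expect_error(flag_irregular(rr_series(c(0, 0.25, 0.5))), "3 R-R")
})

test_that("non-default thresholds and window lengths are honoured", {
  rr_ms <- c(rep(250, 10), 200, rep(250, 10))
  rr <- rr_series(cumsum(c(0, rr_ms)) / 1000)
  expect_false(any(flag_irregular(rr)$suspect))        # 0.8 not < 0.70
  f <- flag_irregular(rr, low = 0.85, high = 1.15)
  expect_equal(sum(f$suspect), 1)
  expect_identical(flag_irregular(rr, window = 5)$suspect,
                   brute_force_flags(rr_ms, window = 5))
})
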