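test_that("a linear age effect is recovered and selected", {
  d <- cohort_design("mouse", n_female = 60, n_male = 60,
                     outcomes = list(y = list(mean = 10, sd = 2,
                                              beta_age = 0.5)))
  co <- simulate_cohort(d, seed = 11)
  tm <- fit_trend(co, "y")
  expect_true("age" %in% tm$terms)
  b <- tm$coefficients$beta[tm$coefficients$term == "age"]
  se <- tm$coefficients$se[tm$coefficients$term == "age"]
  expect_lt(abs(b - 0.5), 2 * se)
  expect_false("age2" %in% tm$terms)
})

test_that("standardization is idempotent: pre-z-scored data gives identical betas", {
  d <- cohort_design("nmr", 50, 50,
                     outcomes = list(y = list(mean = 100, sd = 15,
                                              beta_age = 0.4,
                                              beta_sex = 0.3)))
  co <- simulate_cohort(d, seed = 21)
  tm1 <- fit_trend(co, "y")
  co$y <- as.numeric(scale(co$y))
  tm2 <- fit_trend(co, "y")
  expect_equal(tm1$coefficients$beta, tm2$coefficients$beta,
               tolerance = 1e-12)
  expect_identical(tm1$terms, tm2$terms)
})

test_that("quadratic and sex-specific structures are detected when present", {
  d <- cohort_design("nmr", 80, 80,
                     outcomes = list(
                       q = list(mean = 0, sd = 1, beta_age = -1.0,
                                beta_age2 = 0.9, sigma = 0.5),
                       i = list(mean = 0, sd = 1, beta_age = 0.2,
                                beta_sex = 0.5, sigma = 0.5)))
  co <- simulate_cohort(d, seed = 31)
  tq <- fit_trend(co, "q")
  expect_true(all(c("age", "age2") %in% tq$terms))
  ti <- fit_trend(co, "i")
  expect_true("sex" %in% ti$terms)
})

test_that("degenerate trend inputs are rejected", {
  co <- simulate_cohort(default_cohort_design("mouse"), seed = 1)
  expect_error(fit_trend(co[1:5, ], "qrs_ms"), ">= 10")
  co$const <- 5
  expect_error(fit_trend(co, "const"), "constant")
  expect_error(fit_trend(co, "nope"), "unknown outcome")
})

test_that("AIC selection is available and returns a member of the family", {
  co <- simulate_cohort(default_cohort_design("nmr"), seed = 2)
  tm <- fit_trend(co, "pr_ms", criterion = "aic")
  expect_true(all(tm$terms %in% c("age", "age2", "sex", "age:sex",
                                  "age2:sex")))
  expect_true("aic" %in% names(tm$trace))
})

test_that("wilcoxon p equals full enumeration for tie-free samples", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.10,
               tolerance = 1e-12)
  expect_equal(wilcoxon_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1.0)
  set.seed(41)
  for (k in 1:30) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- sample(1:50, n + m)  # distinct -> tie-free
    a <- x[seq_len(n)]; b <- x[-seq_len(n)]
    got <- wilcoxon_test(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, enumerate_wilcoxon_p(a, b), tolerance = 1e-12)
  }
  expect_error(wilcoxon_test(numeric(0), 1:3), "non-empty")
})

test_that("prevalence arithmetic and bin handling are correct", {
  ev <- data.frame(apb_count = c(1, 2, 0, 0, 0, 0, 0, 0, 0, 0),
                   vpb_count = 0, jpb_count = 0)
  ages <- seq(0.5, 2.3, length.out = 10)
  pv <- arrhythmia_prevalence(ev, ages, bins = c(0, 2.5))
  expect_equal(pv$apb_pct, 20)
  expect_equal(pv$n, 10L)
  # all-zero and all-positive corners
  ev0 <- ev; ev0$apb_count <- 0
  expect_true(all(arrhythmia_prevalence(ev0, ages, c(0, 2.5))$apb_pct == 0))
  ev1 <- data.frame(apb_count = 1, vpb_count = 1, jpb_count = 2)
  pv1 <- arrhythmia_prevalence(ev1, 1.0, c(0, 2))
  expect_equal(unlist(pv1[, c("apb_pct", "vpb_pct", "jpb_pct")]),
               c(apb_pct = 100, vpb_pct = 100, jpb_pct = 100))
  expect_error(arrhythmia_prevalence(ev, ages, bins = c(1, 2)), "outside")
})

test_that("detectable change matches the closed form and its monotonicities", {
  expect_equal(detectable_change(0, 10), 0)
  expect_equal(detectable_change(2.9, 23), 2.396, tolerance = 1e-3)
  expect_equal(detectable_change(6.1, 23), 5.04, tolerance = 1e-2)
  # linear in cv
  cv <- seq(1, 12, by = 0.5)
  mdc <- detectable_change(cv, 23)
  expect_equal(mdc / cv, rep(mdc[1] / cv[1], length(cv)), tolerance = 1e-12)
  # decreasing in n
  ns <- 2:40
  expect_true(all(diff(detectable_change(5, ns)) < 0))
  expect_error(detectable_change(5, 10, alpha = 1.2), "alpha")
  expect_error(detectable_change(5, 10, power = 0), "power")
})
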