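test_that("LVOT area follows the circular-geometry formula", {
  expect_equal(lvot_area(c(2, 2, 2)), pi)
  expect_equal(lvot_area(c(1.8, 2.0, 2.2)), pi) # symmetric mean
  expect_equal(suppressMessages(lvot_area(1.6)), pi * 0.64)
  # rounded-constant worksheet variant
  expect_equal(lvot_area(c(2, 2, 2), pi_const = 3.14), 3.14)
  # scale law: doubling all diameters quadruples the area
  for (seed in 1:20) {
    set.seed(seed)
    d <- runif(3, 1, 3)
    expect_equal(lvot_area(2 * d), 4 * lvot_area(d))
  }
  # strictly increasing in each diameter
  expect_gt(lvot_area(c(2.1, 2, 2)), lvot_area(c(2, 2, 2)))
  expect_error(lvot_area(numeric(0)), class = "hemotrend_input_error")
  expect_error(lvot_area(c(2, -1, 2)), class = "hemotrend_input_error")
})

test_that("echo CO is area x mean VTI x HR with unit conversion", {
  m <- echo_measurement("p", 1, c(2, 2, 2), rep(20, 5), 100)
  out <- echo_cardiac_output(m)
  expect_equal(out$sv_ml, pi * 20, tolerance = 1e-12)
  expect_equal(out$co_lmin, pi * 20 * 100 / 1000, tolerance = 1e-12)

  m2 <- echo_measurement("p", 1, c(2, 2, 2), rep(10, 5), 50)
  out2 <- echo_cardiac_output(m2)
  expect_equal(out2$sv_ml, 31.41593, tolerance = 1e-6)
  expect_equal(out2$co_lmin, 1.570796, tolerance = 1e-6)

  # near-degenerate VTI stays finite and positive, no error
  m3 <- echo_measurement("p", 1, c(2, 2, 2), rep(0.001, 5), 100)
  expect_lt(echo_cardiac_output(m3)$co_lmin, 1e-3)

  # invariance to replicate permutation
  set.seed(42)
  d <- runif(3, 1.6, 2.4); v <- runif(5, 14, 26)
  a <- echo_cardiac_output(echo_measurement("p", 1, d, v, 90))
  b <- echo_cardiac_output(echo_measurement("p", 1, rev(d), sample(v), 90))
  expect_equal(a$co_lmin, b$co_lmin)

  expect_error(echo_measurement("p", 1, c(2, 2, 2), rep(20, 5), -5),
               class = "hemotrend_input_error")
})

test_that("thermodilution CO is the mean of the boluses", {
  expect_equal(pac_cardiac_output(thermodilution_series("p", 1, c(5, 6, 7, 6, 6))), 6)
  expect_equal(pac_cardiac_output(thermodilution_series("p", 1, rep(4, 5))), 4)
  expect_equal(
    pac_cardiac_output(thermodilution_series("p", 1, c(5.2, 5.8, 6.1, 5.9, 6.0))),
    5.8
  )
  expect_error(thermodilution_series("p", 1, 5), class = "hemotrend_input_error")
  expect_message(thermodilution_series("p", 1, c(5, 6, 7)), "nominal is 5")
})

test_that("precision and least significant change follow the k*CV/sqrt(n) convention", {
  # all-constant replicates: zero everywhere
  z <- precision_stats(list(rep(5, 5), rep(7, 5)), "const")
  expect_equal(z$pooled_cv, 0)
  expect_equal(z$precision_pct, 0)
  expect_equal(z$lsc_pct, 0)

  # single subject, hand arithmetic: CV 0.1, n 3
  one <- suppressMessages(precision_stats(list(c(9, 10, 11)), "one"))
  expect_equal(one$pooled_cv, 0.1, tolerance = 1e-12)
  expect_equal(one$precision_pct, 100 * 2 * 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(one$lsc_pct, one$precision_pct * sqrt(2), tolerance = 1e-12)

  # two subjects with known CVs pooled by RMS;
  # construct sets with exact CVs 0.06 and 0.10 via 2-point sets:
  # {m - s, m + s} has mean m, sd = s*sqrt(2), so CV = s*sqrt(2)/m
  mk <- function(cv) {
    s <- cv / sqrt(2)
    c(1 - s, 1 + s)
  }
  two <- suppressMessages(precision_stats(list(mk(0.06), mk(0.10)), "two"))
  expect_equal(two$pooled_cv, sqrt((0.06^2 + 0.10^2) / 2), tolerance = 1e-12)

  # pooling idempotence: k copies of a subject = the single subject
  subj <- c(5.1, 5.9, 6.3, 5.6, 6.1)
  single <- precision_stats(list(subj), "a")
  multi <- precision_stats(rep(list(subj), 7), "a")
  expect_equal(single$pooled_cv, multi$pooled_cv)
  expect_equal(single$precision_pct, multi$precision_pct)

  # arithmetic-mean pooling option
  am <- suppressMessages(precision_stats(list(mk(0.06), mk(0.10)), "two",
                                         pooling = "mean"))
  expect_equal(am$pooled_cv, 0.08, tolerance = 1e-12)

  expect_error(precision_stats(list(c(1, 2), 3), "bad"),
               class = "hemotrend_input_error")
})

test_that("pooled CV recovers the generating replicate CV at scale", {
  set.seed(202)
  cv_true <- 0.09
  sets <- lapply(1:1000, function(i) {
    level <- runif(1, 3, 9)
    level * (1 + rnorm(5, 0, cv_true))
  })
  ps <- precision_stats(sets, "mc")
  expect_lt(abs(ps$pooled_cv - cv_true), 0.005)
})
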