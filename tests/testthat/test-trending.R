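test_that("paired changes are second minus first, percentages on own baseline", {
  t1 <- paired_co(c("a", "b", "c"), 1, c(5, 6, 4), c(5, 6, 4))
  t2 <- paired_co(c("a", "b", "c"), 2, c(6, 6, 3), c(6, 6, 3))
  d <- compute_deltas(t1, t2)
  expect_equal(d$d_ref, c(1, 0, -1))
  expect_equal(d$pct_ref, c(20, 0, -25))
  expect_equal(d$pct_test, c(20, 0, -25))

  # each method tracks its own baseline
  t1b <- paired_co("a", 1, co_ref = 5, co_test = 4)
  t2b <- paired_co("a", 2, co_ref = 6, co_test = 5)
  db <- compute_deltas(t1b, t2b)
  expect_equal(db$pct_ref, 20)
  expect_equal(db$pct_test, 25)

  # unmatched patients skipped with warning
  expect_warning(compute_deltas(t1, t2[1:2, ]), "skipped")
})

test_that("four-quadrant concordance with the central exclusion square", {
  mk <- function(pr, pt) {
    d <- data.frame(patient_id = seq_along(pr), d_ref = pr / 20,
                    d_test = pt / 20, pct_ref = pr, pct_test = pt)
    class(d) <- c("delta_pairs", "data.frame")
    d
  }
  expect_equal(four_quadrant(mk(c(20, -20), c(20, -20)))$concordance_pct, 100)
  expect_equal(four_quadrant(mk(20, -20))$concordance_pct, 0)
  # spec'd 3-point case: (+10,+10) inside the square, one concordant, one not
  fq <- four_quadrant(mk(c(10, 20, 20), c(10, 20, -20)), zone_pct = 15)
  expect_equal(fq$concordance_pct, 50)
  expect_equal(fq$n_included, 2)
  expect_equal(fq$n_excluded, 1)

  # exclusion needs BOTH axes inside the zone
  one_axis <- four_quadrant(mk(c(10, 10), c(20, -20)), zone_pct = 15)
  expect_equal(one_axis$n_included, 2)

  # all-excluded is an explicit degeneracy, not 0
  expect_error(four_quadrant(mk(c(5, -5), c(5, -5)), zone_pct = 15),
               class = "hemotrend_degenerate_error")

  # brute-force oracle on random instances
  for (seed in 1:60) {
    d <- random_deltas(sample(3:40, 1), seed = 400 + seed)
    zone <- sample(c(5, 10, 15, 20), 1)
    expected <- oracle_four_quadrant(d, zone)
    if (is.null(expected)) {
      expect_error(four_quadrant(d, zone), class = "hemotrend_degenerate_error")
    } else {
      got <- four_quadrant(d, zone)
      expect_equal(got$concordance_pct, expected$concordance_pct)
      expect_equal(got$n_included, expected$n_included)
    }
  }
})

test_that("polar transform: angles from the identity line, folding, zone", {
  mk1 <- function(dr, dt) {
    d <- data.frame(patient_id = 1, d_ref = dr, d_test = dt,
                    pct_ref = dr * 20, pct_test = dt * 20)
    class(d) <- c("delta_pairs", "data.frame")
    d
  }
  # concordant increase on the identity line
  p <- polar_transform(mk1(1, 1))
  expect_equal(p$angle_deg, 0)
  expect_equal(p$radius, 1)
  # concordant decrease folds onto the polar axis
  p <- polar_transform(mk1(-1, -1))
  expect_equal(p$angle_deg, 0)
  expect_equal(p$radius, 1)
  # reference-only change: hand trigonometry
  p <- polar_transform(mk1(1, 0))
  expect_equal(p$angle_deg, -45)
  expect_equal(p$radius, 0.5)
  # zone membership: boundary included, below excluded
  expect_false(polar_transform(mk1(0.4, 0.4), zone_lmin = 0.5)$included)
  expect_true(polar_transform(mk1(0.5, 0.5), zone_lmin = 0.5)$included)

  # independent trigonometric recomputation on random points
  d <- random_deltas(200, seed = 555)
  p <- polar_transform(d)
  for (i in seq_len(nrow(d))) {
    expect_equal(p$angle_deg[i], oracle_polar_angle(d$d_ref[i], d$d_test[i]),
                 tolerance = 1e-10)
    expect_equal(p$radius[i], abs((d$d_ref[i] + d$d_test[i]) / 2),
                 tolerance = 1e-12)
  }
  expect_true(all(p$angle_deg > -180 & p$angle_deg <= 180))
})

test_that("polar statistics: mean angle, radial LOA, concordance band", {
  mk <- function(dr, dt) {
    d <- data.frame(patient_id = seq_along(dr), d_ref = dr, d_test = dt,
                    pct_ref = dr * 20, pct_test = dt * 20)
    class(d) <- c("delta_pairs", "data.frame")
    d
  }
  # all on the identity line
  st <- polar_stats(polar_transform(mk(c(1, 2, -1.5), c(1, 2, -1.5))))
  expect_equal(st$mean_angle_deg, 0)
  expect_equal(st$radial_loa_low_deg, 0)
  expect_equal(st$radial_loa_high_deg, 0)
  expect_equal(st$concordance_pct, 100)

  # angles {+10, -10}: sd = 10*sqrt(2), LOA = +/- 27.72
  pol <- data.frame(radius = c(1, 1), angle_deg = c(10, -10),
                    included = c(TRUE, TRUE))
  st <- polar_stats(pol)
  expect_equal(st$mean_angle_deg, 0)
  expect_equal(st$sd_angle_deg, 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(st$radial_loa_high_deg, 1.96 * 10 * sqrt(2), tolerance = 1e-12)

  # a sub-zone point is excluded from every statistic
  pol2 <- rbind(pol, data.frame(radius = 0.4, angle_deg = 90, included = FALSE))
  st2 <- polar_stats(pol2)
  expect_equal(st2$n_included, 2)
  expect_equal(st2$mean_angle_deg, 0)

  # fewer than 2 included points is a named degeneracy
  expect_error(
    polar_stats(data.frame(radius = 0.1, angle_deg = 0, included = FALSE)),
    class = "hemotrend_degenerate_error"
  )
})

test_that("trending invariances: method swap negates angles, scaling preserves them", {
  for (seed in 1:20) {
    d <- random_deltas(sample(5:30, 1), seed = 700 + seed)
    swapped <- d
    swapped$d_ref <- d$d_test; swapped$d_test <- d$d_ref
    swapped$pct_ref <- d$pct_test; swapped$pct_test <- d$pct_ref
    p1 <- polar_transform(d); p2 <- polar_transform(swapped)
    # negation, except the fold boundary at 180
    ok <- abs(abs(p1$angle_deg) - 180) > 1e-9
    expect_equal(p2$angle_deg[ok], -p1$angle_deg[ok], tolerance = 1e-10)
    expect_equal(p2$radius, p1$radius)
    expect_equal(four_quadrant(swapped, 15)$concordance_pct,
                 four_quadrant(d, 15)$concordance_pct)

    k <- runif(1, 0.3, 4)
    scaled <- d
    scaled$d_ref <- k * d$d_ref; scaled$d_test <- k * d$d_test
    scaled$pct_ref <- k * d$pct_ref; scaled$pct_test <- k * d$pct_test
    ps <- polar_transform(scaled)
    expect_equal(ps$angle_deg, p1$angle_deg, tolerance = 1e-10)
    expect_equal(ps$radius, k * p1$radius, tolerance = 1e-10)
  }

  # identical methods: perfect trending for any zone
  d <- random_deltas(20, seed = 42)
  d$d_test <- d$d_ref; d$pct_test <- d$pct_ref
  st <- polar_stats(polar_transform(d, zone_lmin = 0.2))
  expect_equal(st$mean_angle_deg, 0)
  expect_equal(st$concordance_pct, 100)
  expect_equal(four_quadrant(d, 15)$concordance_pct, 100)

  expect_s3_class(plot_four_quadrant(d), "ggplot")
  expect_s3_class(plot_polar(d), "ggplot")
})
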