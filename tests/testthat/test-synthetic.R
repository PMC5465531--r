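test_that("cohort generation is deterministic and respects its design shape", {
  p <- cohort_params(seed = 99)
  a <- suppressMessages(generate_cohort(p))
  b <- suppressMessages(generate_cohort(p))
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth, b$truth)

  # 38 patients, 26 with a second timepoint -> 64 patient-timepoints
  expect_equal(nrow(a$truth), 64)
  expect_equal(sum(a$truth$timepoint == 2), 26)
  expect_equal(length(unique(a$truth$patient_id)), 38)

  # all emitted raw quantities positive
  expect_true(all(a$raw[, -1] > 0))
  expect_true(all(a$truth$true_co > p$co_floor))

  # different seed, different cohort
  c2 <- suppressMessages(generate_cohort(cohort_params(seed = 100)))
  expect_false(identical(a$raw, c2$raw))
})

test_that("noiseless cohorts reconstruct true CO exactly through both methods", {
  p <- cohort_params(
    n_patients = 6, n_change_patients = 3, seed = 5,
    bias_test = 0, sigma_method = 0, cv_rep_ref = 0, cv_rep_test = 0
  )
  coh <- generate_cohort(p)
  der <- derive_co(coh$raw)
  expect_equal(der$co_pac, coh$truth$true_co, tolerance = 1e-10)
  expect_equal(der$co_tte, coh$truth$true_co, tolerance = 1e-10)

  # with a pure offset, the test method reproduces true CO + bias
  p2 <- cohort_params(
    n_patients = 6, n_change_patients = 3, seed = 5,
    bias_test = 0.5, sigma_method = 0, cv_rep_ref = 0, cv_rep_test = 0
  )
  der2 <- derive_co(generate_cohort(p2)$raw)
  expect_equal(der2$co_tte - der2$co_pac, rep(0.5, 9), tolerance = 1e-10)
})

test_that("raw CSV round-trips through the measurement module", {
  coh <- suppressMessages(generate_cohort(cohort_params(n_patients = 5,
                                                        n_change_patients = 2,
                                                        seed = 17)))
  path <- tempfile(fileext = ".csv")
  write_raw_measurements(coh, path)
  df <- read_measurements(path)
  expect_equal(attr(df, "schema"), "raw")
  der <- derive_co(df)
  # reconstruction equals direct computation from the in-memory records
  direct_tte <- vapply(coh$echo, function(m) echo_cardiac_output(m)$co_lmin,
                       numeric(1))
  direct_pac <- vapply(coh$pac, pac_cardiac_output, numeric(1))
  expect_equal(der$co_tte, direct_tte, tolerance = 1e-9)
  expect_equal(der$co_pac, direct_pac, tolerance = 1e-9)

  dpath <- tempfile(fileext = ".csv")
  write_derived_co(der, dpath)
  back <- read_measurements(dpath)
  expect_equal(attr(back, "schema"), "derived")
  expect_equal(back$co_tte, der$co_tte, tolerance = 1e-9)
})

test_that("expected summaries: zero-noise limits and closed-form structure", {
  p0 <- cohort_params(bias_test = 0.3, sigma_method = 0,
                      cv_rep_ref = 0, cv_rep_test = 0)
  es0 <- expected_summaries(p0, n_mc = 1000)
  expect_equal(es0$bias, 0.3)
  expect_equal(es0$sd_diff, 0)
  expect_equal(es0$pe_pct, 0)
  expect_equal(es0$precision_ref_pct, 0)

  # replicate-precision expectation: 100*2*cv/sqrt(n)
  p1 <- cohort_params(cv_rep_ref = 0.09, n_rep_ref = 5)
  es1 <- expected_summaries(p1, n_mc = 1000)
  expect_equal(es1$precision_ref_pct, 100 * 2 * 0.09 / sqrt(5), tolerance = 1e-12)

  # the AUC evaluation is deterministic and leaves the caller's RNG intact
  set.seed(123); before <- rnorm(1)
  set.seed(123); es_a <- expected_summaries(p1, n_mc = 5000)
  after <- rnorm(1)
  expect_equal(before, after)
  es_b <- expected_summaries(p1, n_mc = 5000)
  expect_equal(es_a$auc, es_b$auc)
})

test_that("increasing method disagreement strictly increases the percentage error", {
  pes <- vapply(c(0.02, 0.05, 0.075, 0.12), function(sm) {
    coh <- suppressMessages(generate_cohort(cohort_params(
      n_patients = 400, n_change_patients = 0, sigma_method = sm, seed = 88
    )))
    der <- derive_co(coh$raw)
    pairs <- paired_co(der$patient_id, der$timepoint, der$co_pac, der$co_tte)
    agreement_analysis(pairs)$pe_pct
  }, numeric(1))
  expect_true(all(diff(pes) > 0))
})

test_that("over-rejecting parameterisations are refused", {
  # true-CO mass far below the floor forces heavy rejection
  p_bad <- cohort_params(mu_co = 2.0, sigma_co = 2.0, seed = 1)
  expect_error(suppressMessages(generate_cohort(p_bad)),
               class = "hemotrend_input_error")
  expect_error(cohort_params(n_patients = 0), class = "hemotrend_input_error")
  expect_error(cohort_params(sigma_method = -1), class = "hemotrend_input_error")
})
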