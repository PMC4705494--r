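test_that("noiseless constant parameters give a deterministic constant series", {
  p <- subject_params(mu_rr = 800, a_lf = 0, a_hf = 0, sigma_rr = 0)
  s <- generate_rr_series(p, 300, seed = 1)
  expect_length(s$rr, 375)                 # 375 * 0.8 s = 300 s exactly
  expect_true(all(s$rr == 800))
  expect_equal(s$t, cumsum(s$rr) / 1000)
})

test_that("sample mean of a white-noise series obeys the CLT bound", {
  p <- subject_params(mu_rr = 850, a_lf = 0, a_hf = 0, sigma_rr = 20)
  for (seed in 1:5) {
    s <- generate_rr_series(p, 300, seed = seed)
    n <- length(s$rr)
    expect_lt(abs(mean(s$rr) - 850), 3 * 20 / sqrt(n))
  }
})

test_that("an HF-only modulation concentrates spectral power in the HF band", {
  p <- subject_params(mu_rr = 850, a_lf = 0, a_hf = 30, f_hf = 0.25,
                      sigma_rr = 2)
  s <- generate_rr_series(p, 300, seed = 4)
  sp <- hrv_spectral(s)
  expect_gt(sp$HF, sp$LF)
})

test_that("series generation is reproducible per seed and sensitive to it", {
  p <- subject_params()
  a <- generate_rr_series(p, 120, seed = 7)
  b <- generate_rr_series(p, 120, seed = 7)
  c <- generate_rr_series(p, 120, seed = 8)
  expect_identical(a$rr, b$rr)
  expect_false(identical(a$rr, c$rr))
})

test_that("parameter sets able to produce non-positive intervals are rejected", {
  expect_error(
    generate_rr_series(subject_params(mu_rr = 500, a_lf = 100, a_hf = 100,
                                      sigma_rr = 60), 60, seed = 1),
    "RR <= 0")
  expect_error(subject_params(mu_rr = 100, a_lf = 60, a_hf = 60),
               "mu_rr must exceed")
})

test_that("cohort generation is deterministic and extensible by subject", {
  tm <- true_model(-15, c(MeanRR = 0.05), eps_sd = 1)
  pars3 <- sample_cohort_params(3, seed = 2)
  a <- suppressWarnings(generate_cohort(2, 1, subject_params = pars3[1:2],
                                        model = tm, seed = 2))
  b <- suppressWarnings(generate_cohort(3, 1, subject_params = pars3,
                                        model = tm, seed = 2))
  # same seed, more subjects: the first subjects' data do not reshuffle
  expect_identical(a$instances[[1]]$series$rr, b$instances[[1]]$series$rr)
  expect_identical(a$instances[[2]]$sys_bp, b$instances[[2]]$sys_bp)
  a2 <- suppressWarnings(generate_cohort(2, 1, subject_params = pars3[1:2],
                                         model = tm, seed = 2))
  expect_identical(a$truth, a2$truth)
})

test_that("noiseless cohorts carry a ground truth equal to the planted linear form", {
  tm <- true_model(-18, c(MeanRR = 0.04, RMSSD = 0.3), eps_sd = 0)
  pars <- lapply(sample_cohort_params(3, seed = 9), function(p) {
    p$sigma_bp <- 0
    p
  })
  coh <- suppressWarnings(generate_cohort(3, 2, subject_params = pars,
                                          model = tm, seed = 9))
  lying <- Filter(function(i) i$phase_id == 2L, coh$instances)
  expected <- vapply(lying, function(li) {
    -18 + 0.04 * li$features[["MeanRR"]] + 0.3 * li$features[["RMSSD"]]
  }, numeric(1))
  expect_equal(coh$truth$true_delta_sys, expected, tolerance = 1e-12)
  # and the measured drop reproduces it exactly without BP noise
  ds <- build_predictive_dataset(coh)
  expect_equal(ds$delta_sys, coh$truth$true_delta_sys, tolerance = 1e-9)
})

test_that("mismatched subject parameter lists are rejected", {
  expect_error(
    generate_cohort(3, 1, subject_params = sample_cohort_params(2, 1),
                    model = true_model(-10, c(MeanRR = 0.1))),
    "length 2")
})
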