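test_that("time-domain measures match hand computations", {
  td <- hrv_time_domain(c(800, 860, 865, 920))
  expect_equal(td$RMSSD, sqrt(6650 / 3), tolerance = 1e-12)   # diffs 60, 5, 55
  expect_equal(td$STDNN, sqrt(7218.75 / 3), tolerance = 1e-12)
  expect_equal(td$NN50, 2)
  expect_equal(td$pNN50, 200 / 3, tolerance = 1e-12)
  expect_equal(td$MeanRR, 861.25)
})

test_that("a constant series has zero variability everywhere", {
  td <- hrv_time_domain(rep(800, 100))
  expect_equal(td$STDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$NN50, 0)
  expect_equal(td$pNN50, 0)
  pc <- hrv_poincare(rep(800, 100))
  expect_equal(pc$SD1, 0)
  expect_equal(pc$SD2, 0)
})

test_that("pNN50 is exactly 100 * NN50 / (N - 1) and measures scale linearly", {
  for (seed in 1:10) {
    set.seed(seed)
    rr <- 800 + cumsum(rnorm(80, 0, 30))
    rr <- pmax(rr, 400)
    td <- hrv_time_domain(rr)
    expect_identical(td$pNN50, 100 * td$NN50 / (length(rr) - 1))
    td2 <- hrv_time_domain(2 * rr)
    expect_equal(td2$STDNN, 2 * td$STDNN, tolerance = 1e-12)
    expect_equal(td2$RMSSD, 2 * td$RMSSD, tolerance = 1e-12)
    pc <- hrv_poincare(rr); pc2 <- hrv_poincare(2 * rr)
    expect_equal(pc2$SD1, 2 * pc$SD1, tolerance = 1e-12)
    expect_equal(pc2$SD2, 2 * pc$SD2, tolerance = 1e-12)
  }
})

test_that("Poincare identities hold on arbitrary series", {
  for (seed in 1:20) {
    set.seed(seed)
    rr <- 850 + rnorm(120, 0, 40)
    td <- hrv_time_domain(rr)
    pc <- hrv_poincare(rr)
    sdsd <- sd(diff(rr))
    expect_equal(pc$SD1, sdsd / sqrt(2), tolerance = 1e-9)
    expect_equal(pc$SD1^2 + pc$SD2^2, 2 * td$STDNN^2, tolerance = 1e-9)
  }
  pc <- hrv_poincare(c(800, 860, 865, 920))
  expect_equal(pc$SD1, sd(c(60, 5, 55)) / sqrt(2), tolerance = 1e-12)
})

test_that("triangular measures behave on degenerate and simple histograms", {
  expect_warning(tr <- hrv_triangular(rep(800, 50)), "degenerate")
  expect_equal(tr$HRVtri, 1)
  expect_equal(tr$TINN, 0)
  # two equally filled bins: integral 100 / height 50
  bw <- 1000 / 128
  rr <- rep(c(102.5, 103.5) * bw, each = 50)
  tr2 <- hrv_triangular(rr)
  expect_equal(tr2$HRVtri, 2)
})

test_that("a symmetric triangular histogram yields TINN = base width", {
  bw <- 1000 / 128
  counts <- c(3, 6, 9, 12, 9, 6, 3)          # perfect triangle, base 8 bins
  rr <- rep((102:108 + 0.5) * bw, times = counts)
  tr <- hrv_triangular(rr)
  expect_equal(tr$TINN, 8 * bw, tolerance = 1e-9)
  expect_equal(tr$HRVtri, sum(counts) / 12)
})

test_that("AR band powers land in the modulated band and scale with amplitude^2", {
  base <- function(a_lf, a_hf, seed) {
    generate_rr_series(subject_params(a_lf = a_lf, a_hf = a_hf, f_lf = 0.10,
                                      f_hf = 0.25, sigma_rr = 2),
                       300, seed = seed)
  }
  hf_only <- hrv_spectral(base(0, 30, 5))
  expect_gt(hf_only$HF, 10 * hf_only$LF)
  expect_lt(hf_only$LFHF, 0.1)
  lf_only <- hrv_spectral(base(30, 0, 5))
  expect_gt(lf_only$LF, 10 * lf_only$HF)
  expect_gt(lf_only$LFHF, 10)
  # doubling the amplitude quadruples the band power (+-10%)
  single <- hrv_spectral(base(0, 15, 6))
  double <- hrv_spectral(base(0, 30, 6))
  expect_equal(double$HF / single$HF, 4, tolerance = 0.1)
})

test_that("short or degenerate inputs for spectral analysis are rejected", {
  expect_error(hrv_spectral(rep(800, 50)), "2 minutes")
  flat <- hrv_spectral(rep(800, 200))
  expect_equal(flat$LF, 0)
  expect_equal(flat$HF, 0)
  expect_true(is.na(flat$LFHF))
})

test_that("the assembled feature vector has the 22 standard names in order", {
  s <- generate_rr_series(subject_params(), 300, seed = 2)
  f <- hrv_features(s)
  expect_length(f, 22)
  expect_identical(names(f), hrv_feature_names)
  expect_length(hrv_feature_names, 22)
  # deterministic across repeated extraction
  expect_identical(f, hrv_features(generate_rr_series(subject_params(), 300,
                                                      seed = 2)))
})

test_that("features that cannot be computed are missing with a reason, never zero", {
  f <- suppressWarnings(hrv_features(rr_series(rep(800, 150))))
  expect_equal(unname(f["MeanRR"]), 800)
  expect_equal(unname(f["STDNN"]), 0)
  # too short for D2 (needs 200), degenerate for SampEn-adjacent measures
  expect_true(is.na(f["D2"]))
  reasons <- attr(f, "missing_reasons")
  expect_true("D2" %in% names(reasons))
  expect_false(any(is.na(f[c("MeanRR", "STDNN", "RMSSD", "NN50", "pNN50")])))
})
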