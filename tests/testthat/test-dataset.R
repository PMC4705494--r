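test_that("the standing drop is the second-minute reading minus the lying mean", {
  expect_equal(compute_delta_bp(115, c(120, 122, 118, 120)), -5)
  expect_equal(compute_delta_bp(120, c(120, 120, 120, 120)), 0)
  expect_error(compute_delta_bp(115, c(120, 122, 118)), "4 lying")
  expect_error(compute_delta_bp(NA, c(120, 122, 118, 120)), "missing")
})

test_that("the propagated drop measurement error follows NE + NE/sqrt(n)", {
  expect_identical(delta_bp_error(3, 4), 4.5)
  expect_identical(delta_bp_error(0, 7), 0)
  expect_identical(delta_bp_error(3, 1), 6)
  expect_error(delta_bp_error(3, 0), "positive integer")
  expect_error(delta_bp_error(-1, 4), "non-negative")
})

test_that("predictive instances pair lying features with the matching standing drop", {
  # hand-built instances: distinct feature vectors per phase expose provenance
  feat <- function(v) setNames(rep(v, 22), hrv_feature_names)
  inst <- list(
    list(sub_id = 1, phase_id = 2L, test_id = 1, symptom_id = 0L,
         sys_bp = c(120, 121, 119, 120), dia_bp = c(80, 80, 80, 80),
         series = NULL, features = feat(1)),
    list(sub_id = 1, phase_id = 3L, test_id = 1, symptom_id = 0L,
         sys_bp = c(118, 112, 113, 114), dia_bp = c(80, 78, 79, 78),
         series = NULL, features = feat(99))
  )
  ds <- build_predictive_dataset(inst)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$delta_sys, 112 - 120)
  expect_equal(ds$delta_dia, 78 - 80)
  expect_true(all(ds[1, hrv_feature_names] == 1))   # lying features only
})

test_that("unmatched repetitions are skipped with a warning", {
  tm <- true_model(-15, c(MeanRR = 0.05), eps_sd = 0)
  coh <- suppressWarnings(generate_cohort(3, 2, model = tm, seed = 21))
  full <- build_predictive_dataset(coh)
  expect_equal(nrow(full), 6)
  # drop one standing instance
  keep <- !vapply(coh$instances, function(i) {
    i$sub_id == 2 && i$phase_id == 3L && i$test_id == 1
  }, logical(1))
  coh$instances <- coh$instances[keep]
  expect_warning(partial <- build_predictive_dataset(coh), "skipped")
  expect_equal(nrow(partial), 5)
})

test_that("cohort CSVs round-trip and schema violations name the row", {
  tm <- true_model(-15, c(MeanRR = 0.05), eps_sd = 1)
  coh <- suppressWarnings(generate_cohort(2, 1, model = tm, seed = 33))
  dir <- tempfile("csv")
  write_cohort_csv(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("rr.csv", "bp.csv",
                                               "truth.csv")))))
  back <- read_cohort_csv(file.path(dir, "rr.csv"), file.path(dir, "bp.csv"))
  expect_equal(length(back$instances), length(coh$instances))
  orig <- coh$instances[[2]]
  match_i <- Filter(function(i) {
    i$sub_id == orig$sub_id && i$phase_id == orig$phase_id &&
      i$test_id == orig$test_id
  }, back$instances)[[1]]
  expect_equal(match_i$series$rr, orig$series$rr, tolerance = 1e-9)
  expect_equal(match_i$sys_bp, orig$sys_bp, tolerance = 1e-9)
  # corrupt a BP value outside the physiological range
  bp <- read.csv(file.path(dir, "bp.csv"))
  bp$sys_mmhg[3] <- 300
  write.csv(bp, file.path(dir, "bp.csv"), row.names = FALSE)
  expect_error(read_bp_csv(file.path(dir, "bp.csv")), "row\\(s\\) 3")
  expect_error(read_rr_csv(file.path(dir, "bp.csv")), "missing column")
})
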