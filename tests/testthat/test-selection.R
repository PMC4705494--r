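test_that("sigma_est matches its closed form and scales with residuals", {
  expect_equal(sigma_est(c(10, 12, 8), c(11, 11, 9)), sqrt(3), tolerance = 1e-12)
  expect_equal(sigma_est(1:5, 1:5), 0)
  set.seed(1)
  y <- rnorm(10); p <- rnorm(10)
  expect_equal(sigma_est(y, y + 2 * (p - y) / 1), 2 * sigma_est(y, p),
               tolerance = 1e-12)
  expect_error(sigma_est(1:2, 1:2), "at least 3")
})

test_that("LOSO folds hold out whole subjects and average per-fold sigma", {
  df <- make_pred_frame(10, 4, c("f1", "f2"), function(d) {
    5 + 2 * d$f1 - d$f2 + rnorm(nrow(d), 0, 0.5)
  }, seed = 7)
  s <- loso_cv(df, c("f1", "f2"))
  folds <- attr(s, "fold_sigma")
  preds <- attr(s, "predictions")
  expect_length(folds, 10)
  expect_false(any(is.na(preds)))
  expect_equal(as.numeric(s), mean(folds), tolerance = 1e-12)
  # fold-order invariance
  shuf <- df[sample(nrow(df)), ]
  expect_equal(as.numeric(loso_cv(shuf, c("f1", "f2"))), as.numeric(s),
               tolerance = 1e-9)
})

test_that("duplicate subjects with a noiseless linear response give zero LOSO error", {
  base <- make_pred_frame(1, 4, c("f1",  "f2"), function(d) 1 + d$f1, seed = 3)
  df <- do.call(rbind, lapply(1:4, function(s) {
    b <- base; b$sub_id <- s; b
  }))
  df$delta_sys <- 1 + df$f1
  expect_equal(as.numeric(loso_cv(df, "f1")), 0, tolerance = 1e-9)
})

test_that("subset enumeration covers all combinations of size 1..5", {
  expect_equal(nrow(hrvdrop:::enumerate_subsets(22, 5)),
               sum(choose(22, 1:5)))   # 35,442
  expect_equal(nrow(hrvdrop:::enumerate_subsets(6, 2)), 21)
})

test_that("the compiled search equals a brute-force re-enumeration", {
  feats <- c("f1", "f2", "f3", "f4", "f5", "f6")
  df <- make_pred_frame(5, 3, feats, function(d) {
    -4 + 1.5 * d$f2 - 0.8 * d$f5 + rnorm(nrow(d), 0, 0.4)
  }, seed = 13)
  got <- exhaustive_search(df, max_k = 2, features = feats, keep_scores = TRUE)
  # independent enumeration through the R-level LOSO path
  subsets <- c(lapply(feats, identity),
               combn(feats, 2, simplify = FALSE))
  scores <- vapply(subsets, function(ss) as.numeric(loso_cv(df, ss)),
                   numeric(1))
  expect_equal(length(subsets), got$n_subsets)
  best <- which.min(scores)
  expect_identical(got$best_subset, subsets[[best]])
  expect_equal(got$best_score, scores[best], tolerance = 1e-9)
  expect_equal(got$scores$score, scores, tolerance = 1e-9)
})

test_that("a planted single-feature response is selected at max_k = 1", {
  df <- make_pred_frame(6, 3, c("MeanRR", "STDNN", "RMSSD"), function(d) {
    0.5 * d$MeanRR + rnorm(nrow(d), 0, 0.2)
  }, seed = 5)
  got <- exhaustive_search(df, max_k = 1,
                           features = c("MeanRR", "STDNN", "RMSSD"))
  expect_identical(got$best_subset, "MeanRR")
})

test_that("features with missing values are excluded from the candidate pool", {
  df <- make_pred_frame(5, 2, c("f1", "f2", "f3"), function(d) {
    2 * d$f1 + rnorm(nrow(d), 0, 0.3)
  }, seed = 8)
  df$f3[4] <- NA
  expect_message(got <- exhaustive_search(df, max_k = 2,
                                          features = c("f1", "f2", "f3")),
                 "missing values: f3")
  expect_false("f3" %in% got$candidates)
})

test_that("percent correct applies a strict threshold", {
  m <- c(0, 0, 0, 0)
  p <- c(0, 4, 5, 10)
  expect_equal(percent_correct(m, p, 4.5), 50)
  expect_equal(percent_correct(1:5, 1:5), 100)
  expect_equal(percent_correct(1:5, 1:5 + 0.01, 0), 0)
  expect_equal(percent_correct(c(0, 0), c(4.5, 0), 4.5), 50)  # boundary incorrect
})

test_that("false negative/positive rates follow the drop conventions", {
  # prediction far below the measured drop: missed severity, false negative
  r <- fp_fn_rates(measured = -5, predicted = -12)
  expect_equal(r$fn_rate, 100)
  expect_equal(r$fp_rate, 0)
  r2 <- fp_fn_rates(measured = -10, predicted = -2)
  expect_equal(r2$fp_rate, 100)
  r3 <- fp_fn_rates(1:10, 1:10)
  expect_equal(r3$fn_rate, 0)
  expect_equal(r3$fp_rate, 0)
})

test_that("correctness, FP, FN and the boundary band account for every instance", {
  set.seed(6)
  m <- rnorm(200, 0, 6)
  p <- m + rnorm(200, 0, 5)
  pc <- percent_correct(m, p, 4.5)
  r <- fp_fn_rates(m, p, 5)
  band <- 100 * mean(abs(m - p) >= 4.5 & abs(m - p) <= 5)
  expect_equal(pc + r$fn_rate + r$fp_rate + band, 100, tolerance = 1e-9)
})

test_that("the residual histogram is symmetric, centred and sums to 100", {
  h0 <- residual_histogram(rep(0, 8))
  expect_equal(h0$percent[h0$center == 0], 100)
  h <- residual_histogram(c(-3, 0, 0, 3))
  expect_equal(h$percent[h$center == 0], 50)
  expect_equal(sum(h$percent), 100)
  set.seed(2)
  hr <- residual_histogram(rnorm(500, 0, 4))
  expect_equal(sum(hr$percent), 100, tolerance = 1e-9)
  expect_equal(hr$center, -rev(hr$center))   # symmetric bin layout
})
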