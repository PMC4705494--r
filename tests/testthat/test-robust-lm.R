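test_that("exact linear data is recovered exactly, regardless of weights", {
  x <- matrix(1:20, ncol = 1, dimnames = list(NULL, "f"))
  y <- 2 + 3 * x[, 1]
  fit <- fit_robust(x, y)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("a gross outlier is down-weighted far below the OLS error", {
  x <- matrix(1:20, ncol = 1, dimnames = list(NULL, "f"))
  y <- 2 + 3 * x[, 1]
  y[10] <- y[10] + 100
  robust_err <- abs(coef(fit_robust(x, y))[["f"]] - 3)
  ols_err <- abs(coef(lm(y ~ x))[[2]] - 3)
  expect_lt(robust_err, ols_err)
  expect_lt(robust_err, 1e-6)   # bisquare gives the outlier zero weight here
})

test_that("the fit is invariant under permutation of instances", {
  set.seed(4)
  X <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(30)
  y[5] <- y[5] + 30
  fit <- fit_robust(X, y)
  perm <- sample(30)
  fit_p <- fit_robust(X[perm, ], y[perm])
  expect_equal(coef(fit), coef(fit_p), tolerance = 1e-9)
})

test_that("the compiled IRLS agrees exactly with an R-native reimplementation", {
  set.seed(11)
  for (rep in 1:3) {
    X <- cbind(rnorm(40), runif(40, 0, 5))
    colnames(X) <- c("u", "v")
    y <- 3 - 2 * X[, 1] + 0.5 * X[, 2] + rnorm(40)
    y[c(3, 17)] <- y[c(3, 17)] + c(25, -40)
    got <- unname(coef(fit_robust(X, y)))
    want <- oracle_irls(cbind(1, X), y)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("coefficients agree closely with an independent M-estimator", {
  skip_if_not_installed("MASS")
  set.seed(2)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  y <- 1 + 2 * X[, 1] - 3 * X[, 2] + rnorm(60)
  y[c(5, 40)] <- y[c(5, 40)] + c(20, -20)
  ours <- unname(coef(fit_robust(X, y)))
  mass <- unname(coef(MASS::rlm(y ~ X, psi = MASS::psi.bisquare, c = 4.685,
                                maxit = 100)))
  expect_equal(ours, mass, tolerance = 0.05)
})

test_that("rank-deficient designs fail with the collinear feature named", {
  X <- cbind(a = 1:20, b = 2 * (1:20))
  y <- rnorm(20)
  expect_error(fit_robust(X, y), "collinear.*b")
  expect_error(fit_robust(cbind(a = c(1, NA, 3:20)), rnorm(20)), "missing")
  expect_error(fit_robust(cbind(a = 1:2), 1:2), "more instances")
})

test_that("prediction evaluates the linear form by feature name", {
  m <- model_from_json(jsonlite::toJSON(list(
    feature_names = c("RMSSD", "NN50", "TINN", "HF", "RPDET"),
    coefficients = list("(Intercept)" = -25.67, RMSSD = 0.45, NN50 = -0.05,
                        TINN = -0.02, HF = -0.01, RPDET = 0.3),
    tuning = 4.685, converged = TRUE, iterations = 1, n = 40),
    auto_unbox = TRUE))
  zero <- data.frame(RMSSD = 0, NN50 = 0, TINN = 0, HF = 0, RPDET = 0)
  expect_equal(predict(m, zero), -25.67)
  pt <- data.frame(RMSSD = 40, NN50 = 60, TINN = 200, HF = 500, RPDET = 95)
  expect_equal(predict(m, pt), -25.67 + 18 - 3 - 4 - 5 + 28.5,
               tolerance = 1e-12)
  expect_error(predict(m, zero[, -1]), "lacks feature")
})

test_that("models survive a JSON round-trip", {
  set.seed(9)
  X <- cbind(RMSSD = runif(30, 10, 60), HF = runif(30, 100, 900))
  y <- -20 + 0.4 * X[, 1] - 0.01 * X[, 2] + rnorm(30)
  fit <- fit_robust(X, y)
  path <- tempfile(fileext = ".json")
  model_to_json(fit, path)
  back <- model_from_json(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  nd <- data.frame(RMSSD = 30, HF = 400)
  expect_equal(predict(back, nd), predict(fit, nd), tolerance = 1e-12)
})
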