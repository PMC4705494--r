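#' Regression standard error
#'
#' `sigma_est = sqrt( sum((Y - Y')^2) / (N - 2) )`: the average distance
#' between measured and predicted drops, in mmHg.
#'
#' @param measured,predicted numeric vectors of equal length `N >= 3`.
#' @return sigma_est (mmHg).
#' @examples
#' sigma_est(c(10, 12, 8), c(11, 11, 9))  # sqrt(3)
#' @export
sigma_est <- function(measured, predicted) {
  if (length(measured) != length(predicted)) stop("length mismatch")
  n <- length(measured)
  if (n <= 2) stop("need at least 3 instances")
  sqrt(sum((measured - predicted)^2) / (n - 2))
}

#' Leave-one-subject-out cross-validated sigma_est
#'
#' One fold per subject: the robust model is fitted on all other
#' subjects' instances and scored on the held-out subject. In
#' `"per_fold"` mode (default) each fold's sigma_est is computed with
#' that fold's own instance count (denominator guarded as
#' `max(N - 2, 1)`) and the unweighted mean across folds is returned; in
#' `"pooled"` mode the held-out residuals are pooled and a single
#' sigma_est over all N instances is returned.
#'
#' @param data predictive data.frame (one row per instance) containing
#'   `subject` and `outcome` columns and the feature columns.
#' @param subset character vector of feature names to fit.
#' @param outcome name of the response column; default `"delta_sys"`.
#' @param subject name of the subject-id column; default `"sub_id"`.
#' @param tuning,tol,max_iter passed to [fit_robust()].
#' @param mode `"per_fold"` or `"pooled"`.
#' @return mean sigma_est (mmHg); per-fold values in attribute
#'   `"fold_sigma"`, out-of-fold predictions in attribute `"predictions"`.
#' @export
loso_cv <- function(data, subset, outcome = "delta_sys", subject = "sub_id",
                    tuning = 4.685, tol = 1e-8, max_iter = 50L,
                    mode = c("per_fold", "pooled")) {
  mode <- match.arg(mode)
  subjects <- unique(data[[subject]])
  if (length(subjects) < 3) stop("need at least 3 subjects")
  y <- data[[outcome]]
  preds <- rep(NA_real_, nrow(data))
  fold_sigma <- numeric(length(subjects))
  for (k in seq_along(subjects)) {
    hold <- data[[subject]] == subjects[k]
    fit <- fit_robust(data[!hold, subset, drop = FALSE], y[!hold],
                      tuning = tuning, tol = tol, max_iter = max_iter)
    preds[hold] <- predict(fit, data[hold, subset, drop = FALSE])
    nt <- sum(hold)
    fold_sigma[k] <- sqrt(sum((y[hold] - preds[hold])^2) / max(nt - 2, 1))
  }
  out <- if (mode == "per_fold") {
    mean(fold_sigma)
  } else {
    sqrt(sum((y - preds)^2) / max(length(y) - 2, 1))
  }
  attr(out, "fold_sigma") <- fold_sigma
  attr(out, "predictions") <- preds
  out
}

# Enumerate all subsets of features of size 1..max_k as a 0-padded integer
# matrix of column indices (in the given feature order).
enumerate_subsets <- function(n_features, max_k) {
  mats <- lapply(seq_len(max_k), function(k) {
    cmb <- t(combn(n_features, k))
    cbind(cmb, matrix(0L, nrow(cmb), max_k - k))
  })
  storage.mode(mats[[1]]) <- "integer"
  out <- do.call(rbind, mats)
  storage.mode(out) <- "integer"
  out
}

#' Exhaustive feature-subset search under LOSO cross-validation
#'
#' Evaluates every subset of 1 to `max_k` candidate features by
#' leave-one-subject-out cross-validated [sigma_est()] (22 candidates and
#' `max_k = 5` give 35,442 subsets), selects the minimiser — ties broken
#' towards the smaller subset, then lexicographic feature order — and
#' refits the winning subset on the whole dataset. Features with missing
#' values are excluded from the candidate pool with a message; subsets
#' whose fit fails score `Inf`.
#'
#' @inheritParams loso_cv
#' @param features candidate feature names; default [hrv_feature_names].
#' @param max_k largest subset size; default 5.
#' @param keep_scores if `TRUE`, return the full score table.
#' @return object of class `subset_search`: list with `best_subset`,
#'   `best_score` (mean LOSO sigma_est, mmHg), `model` (final
#'   [fit_robust()] on all instances), `n_subsets`, and optionally
#'   `scores` (data.frame subset/k/score).
#' @export
exhaustive_search <- function(data, max_k = 5, features = hrv_feature_names,
                              outcome = "delta_sys", subject = "sub_id",
                              tuning = 4.685, tol = 1e-8, max_iter = 50L,
                              mode = c("per_fold", "pooled"),
                              keep_scores = FALSE) {
  mode <- match.arg(mode)
  if (max_k > 5) stop("max_k must not exceed 5")
  features <- intersect(features, names(data))
  usable <- features[vapply(features, function(f) {
    all(is.finite(data[[f]]))
  }, logical(1))]
  dropped <- setdiff(features, usable)
  if (length(dropped) > 0) {
    message("excluding feature(s) with missing values: ",
            paste(dropped, collapse = ", "))
  }
  if (length(usable) == 0) stop("no usable candidate features")
  F <- as.matrix(data[usable])
  storage.mode(F) <- "double"
  y <- as.numeric(data[[outcome]])
  subjects <- unique(data[[subject]])
  if (length(subjects) < 3) stop("need at least 3 subjects")
  fold <- as.integer(match(data[[subject]], subjects) - 1L)
  subsets <- enumerate_subsets(length(usable), min(max_k, length(usable)))
  scores <- loso_scores_cpp(F, y, fold, subsets, tuning, tol,
                            as.integer(max_iter), mode == "pooled")
  k <- rowSums(subsets > 0)
  # tie-break: score, then smaller k, then lexicographic feature order
  ord <- do.call(order, c(list(scores, k),
                          lapply(seq_len(ncol(subsets)),
                                 function(j) subsets[, j])))
  best_i <- ord[1]
  if (!is.finite(scores[best_i])) stop("no subset could be fitted")
  best_subset <- usable[subsets[best_i, subsets[best_i, ] > 0]]
  model <- fit_robust(data[best_subset], y, tuning = tuning, tol = tol,
                      max_iter = max_iter)
  out <- list(best_subset = best_subset,
              best_score = scores[best_i],
              model = model,
              n_subsets = nrow(subsets),
              candidates = usable)
  if (keep_scores) {
    out$scores <- data.frame(
      subset = apply(subsets, 1, function(r) {
        paste(usable[r[r > 0]], collapse = "+")
      }),
      k = k, score = scores)
  }
  class(out) <- "subset_search"
  out
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("Exhaustive LOSO subset search over %d subsets (%d candidates)\n",
              x$n_subsets, length(x$candidates)))
  cat(sprintf("  best subset: %s\n", paste(x$best_subset, collapse = ", ")))
  cat(sprintf("  mean LOSO sigma_est: %.4f mmHg\n", x$best_score))
  invisible(x)
}

#' Percentage of correctly predicted drops
#'
#' A prediction counts as correct when its absolute error is strictly
#' below the measurement error of the drop; an error exactly equal to the
#' threshold counts as incorrect.
#'
#' @param measured,predicted numeric vectors of equal length.
#' @param error_threshold correctness threshold (mmHg); default the
#'   4.5 mmHg cuff-propagated error ([delta_bp_error()] at NE = 3, n = 4).
#' @return percentage in `[0, 100]`.
#' @export
percent_correct <- function(measured, predicted, error_threshold = 4.5) {
  if (length(measured) != length(predicted)) stop("length mismatch")
  if (length(measured) == 0) stop("empty input")
  100 * mean(abs(measured - predicted) < error_threshold)
}

#' False-negative and false-positive rates of the drop prediction
#'
#' A false negative underestimates the drop: predicted drop below
#' `measured - margin` (the model misses how far pressure falls, the
#' clinically dangerous direction). A false positive overestimates:
#' predicted above `measured + margin` (a spurious alarm).
#'
#' @param measured,predicted numeric vectors of equal length.
#' @param margin tolerance (mmHg); default 5.
#' @return named list: `fn_rate`, `fp_rate` (percent).
#' @export
fp_fn_rates <- function(measured, predicted, margin = 5) {
  if (length(measured) != length(predicted)) stop("length mismatch")
  list(fn_rate = 100 * mean(predicted < measured - margin),
       fp_rate = 100 * mean(predicted > measured + margin))
}

#' Residual histogram with symmetric bins centred on zero
#'
#' @param residuals numeric vector of measured - predicted drops (mmHg).
#' @param bin_width bin width (mmHg); default 2. Bins are centred on 0,
#'   so the central bin spans `(-bin_width/2, bin_width/2]`.
#' @return data.frame: `lower`, `upper`, `center` (mmHg), `count`,
#'   `percent`; the percentages sum to 100.
#' @export
residual_histogram <- function(residuals, bin_width = 2) {
  if (length(residuals) == 0) stop("empty residuals")
  # assign each residual to its nearest bin centre (0, +-bw, +-2bw, ...)
  idx <- round(residuals / bin_width)
  kmax <- max(abs(idx))
  ks <- seq(-kmax, kmax)
  centers <- ks * bin_width
  counts <- vapply(ks, function(k) sum(idx == k), numeric(1))
  data.frame(
    lower = centers - bin_width / 2,
    upper = centers + bin_width / 2,
    center = centers,
    count = counts,
    percent = 100 * counts / length(residuals)
  )
}
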