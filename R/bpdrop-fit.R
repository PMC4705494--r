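#' Fit the orthostatic BP-drop prediction model
#'
#' The package's central fitter. Given a predictive dataset — one row per
#' (subject, repetition) holding the lying-phase HRV features and the
#' measured systolic/diastolic drop on standing — it runs the exhaustive
#' feature-subset search under leave-one-subject-out (LOSO)
#' cross-validation, refits the winning subset on all instances with the
#' robust bisquare regression, and assembles the evaluation report:
#' cross-validated, training and whole-dataset regression standard errors,
#' the percentage of correctly predicted drops, false-negative /
#' false-positive rates and the residual distribution.
#'
#' %CP, the FP/FN rates and the residuals are computed from the final
#' whole-dataset model's predictions; the LOSO out-of-fold predictions for
#' the winning subset are kept in `$loso_predictions` for honest
#' generalisation checks.
#'
#' @param data predictive data.frame, e.g. from
#'   [build_predictive_dataset()].
#' @param outcome response column; default `"delta_sys"` (the systolic
#'   drop is the modelled outcome; diastolic is stored but not modelled by
#'   default).
#' @param features candidate feature columns; default the 22 HRV measures.
#' @param max_k largest subset size; default 5.
#' @param subject subject-id column; default `"sub_id"`.
#' @param error_threshold correctness threshold for %CP (mmHg); default
#'   4.5, the cuff-propagated drop error.
#' @param margin FP/FN margin (mmHg); default 5 (kept distinct from
#'   `error_threshold` on purpose — they answer different questions).
#' @param tuning bisquare tuning constant; default 4.685.
#' @param sigma_mode `"per_fold"` (default) or `"pooled"` LOSO sigma.
#' @param hist_bin_width residual-histogram bin width (mmHg); default 2.
#' @param keep_scores keep the full subset score table.
#' @return object of class `bpdrop_fit` with elements `model`
#'   (`robust_lm`), `best_subset`, `report` (list: `sigma_est_test`,
#'   `sigma_est_train`, `sigma_est_full`, `percent_correct`, `fp_rate`,
#'   `fn_rate`, `residuals`, `residual_hist`, `best_subset`, `n`),
#'   `search`, `loso_predictions`, `data`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(4, 2, seed = 42)
#' ds <- build_predictive_dataset(coh)
#' fit <- bpdrop_fit(ds, max_k = 2, features = c("MeanRR", "RMSSD", "HF"))
#' print(fit)
#' }
#' @export
bpdrop_fit <- function(data, outcome = "delta_sys",
                       features = hrv_feature_names, max_k = 5,
                       subject = "sub_id", error_threshold = 4.5,
                       margin = 5, tuning = 4.685,
                       sigma_mode = c("per_fold", "pooled"),
                       hist_bin_width = 2, keep_scores = FALSE) {
  sigma_mode <- match.arg(sigma_mode)
  search <- exhaustive_search(data, max_k = max_k, features = features,
                              outcome = outcome, subject = subject,
                              tuning = tuning, mode = sigma_mode,
                              keep_scores = keep_scores)
  y <- data[[outcome]]
  model <- search$model
  pred_full <- predict(model, data[search$best_subset])
  resid_full <- y - pred_full

  # LOSO once more on the winner for fold detail + training-side sigma
  subjects <- unique(data[[subject]])
  train_sigma <- numeric(length(subjects))
  loso_pred <- rep(NA_real_, nrow(data))
  for (k in seq_along(subjects)) {
    hold <- data[[subject]] == subjects[k]
    fit_k <- fit_robust(data[!hold, search$best_subset, drop = FALSE],
                        y[!hold], tuning = tuning)
    train_sigma[k] <- sigma_est(y[!hold], fit_k$fitted)
    loso_pred[hold] <- predict(fit_k, data[hold, search$best_subset,
                                           drop = FALSE])
  }
  rates <- fp_fn_rates(y, pred_full, margin)
  report <- list(
    sigma_est_test = search$best_score,
    sigma_est_train = mean(train_sigma),
    sigma_est_full = sigma_est(y, pred_full),
    percent_correct = percent_correct(y, pred_full, error_threshold),
    fp_rate = rates$fp_rate,
    fn_rate = rates$fn_rate,
    residuals = resid_full,
    residual_hist = residual_histogram(resid_full, hist_bin_width),
    best_subset = search$best_subset,
    n = nrow(data)
  )
  structure(list(model = model, best_subset = search$best_subset,
                 report = report, search = search,
                 loso_predictions = loso_pred,
                 outcome = outcome, subject = subject,
                 error_threshold = error_threshold, margin = margin,
                 data = data),
            class = "bpdrop_fit")
}

#' @export
print.bpdrop_fit <- function(x, ...) {
  r <- x$report
  cat("Orthostatic BP-drop model (robust regression + exhaustive LOSO search)\n")
  cat(sprintf("  selected features: %s\n", paste(x$best_subset, collapse = ", ")))
  cat("  coefficients:\n")
  print(round(coef(x$model), 4))
  cat(sprintf("  sigma_est [mmHg]  test %.2f | train %.2f | full %.2f\n",
              r$sigma_est_test, r$sigma_est_train, r$sigma_est_full))
  cat(sprintf("  correct predictions (|err| < %.1f mmHg): %.1f%%\n",
              x$error_threshold, r$percent_correct))
  cat(sprintf("  false negatives %.1f%% | false positives %.1f%% (margin %.0f mmHg)\n",
              r$fn_rate, r$fp_rate, x$margin))
  invisible(x)
}

#' @export
summary.bpdrop_fit <- function(object, ...) {
  print(object)
  cat("\nresidual histogram (% per 2 mmHg bin):\n")
  h <- object$report$residual_hist
  print(data.frame(center = h$center, percent = round(h$percent, 1)))
  invisible(object)
}

#' @export
coef.bpdrop_fit <- function(object, ...) coef(object$model)

#' @export
residuals.bpdrop_fit <- function(object, ...) object$report$residuals

#' @export
fitted.bpdrop_fit <- function(object, ...) fitted(object$model)

#' @export
predict.bpdrop_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$model))
  predict(object$model, newdata)
}

#' Plot the residual histogram of a fitted BP-drop model
#'
#' @param x a `bpdrop_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bpdrop_fit <- function(x, ...) {
  h <- x$report$residual_hist
  graphics::barplot(h$percent, names.arg = h$center,
                    xlab = "prediction error (mmHg)",
                    ylab = "% of predictions", ...)
  invisible(x)
}

#' Write an evaluation report to JSON and per-instance CSV
#'
#' @param fit a [bpdrop_fit()].
#' @param dir output directory.
#' @return invisibly, the paths written (`report.json`,
#'   `predictions.csv`, `residual_histogram.csv`).
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "bpdrop_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- fit$report
  paths <- c(report = file.path(dir, "report.json"),
             predictions = file.path(dir, "predictions.csv"),
             hist = file.path(dir, "residual_histogram.csv"))
  obj <- list(best_subset = r$best_subset,
              sigma_est_test = r$sigma_est_test,
              sigma_est_train = r$sigma_est_train,
              sigma_est_full = r$sigma_est_full,
              percent_correct = r$percent_correct,
              fp_rate = r$fp_rate, fn_rate = r$fn_rate,
              n = r$n)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths["report"])
  y <- fit$data[[fit$outcome]]
  write.csv(data.frame(
    sub_id = fit$data[[fit$subject]],
    test_id = fit$data$test_id,
    measured = y,
    predicted = predict(fit),
    residual = r$residuals,
    loso_predicted = fit$loso_predictions
  ), paths["predictions"], row.names = FALSE)
  write.csv(r$residual_hist, paths["hist"], row.names = FALSE)
  invisible(paths)
}
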