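#' BP drop on standing
#'
#' The orthostatic blood-pressure change is the reading taken during the
#' second minute after the standing action minus the mean of the four
#' lying readings. Negative values are drops.
#'
#' @param standing_bp_minute2 the second-minute standing reading (mmHg).
#' @param lying_bps exactly 4 lying readings (mmHg).
#' @return delta BP (mmHg).
#' @examples
#' compute_delta_bp(115, c(120, 122, 118, 120))  # -5
#' @export
compute_delta_bp <- function(standing_bp_minute2, lying_bps) {
  if (length(standing_bp_minute2) != 1 || is.na(standing_bp_minute2)) {
    stop("standing reading missing")
  }
  if (length(lying_bps) != 4 || any(is.na(lying_bps))) {
    stop("exactly 4 lying readings required")
  }
  standing_bp_minute2 - mean(lying_bps)
}

#' Measurement error of the BP drop
#'
#' Error propagated from the cuff device's nominal error `NE` through the
#' drop computation: the standing reading contributes `NE` and the mean of
#' `n` repeated lying readings contributes `NE / sqrt(n)`, giving
#' `NE + NE / sqrt(n)`. With the common 3 mmHg nominal error and 4 lying
#' readings the bound is 4.5 mmHg.
#'
#' @param nominal_error device nominal error NE (mmHg); >= 0.
#' @param n number of repeated lying measurements; integer >= 1.
#' @return error bound on the measured drop (mmHg).
#' @examples
#' delta_bp_error(3, 4)  # 4.5
#' @export
delta_bp_error <- function(nominal_error, n) {
  if (nominal_error < 0) stop("nominal_error must be non-negative")
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  nominal_error + nominal_error / sqrt(n)
}

#' Build the predictive dataset from a raw cohort
#'
#' Pairs each lying instance's HRV features with the systolic and
#' diastolic drops computed from the matching standing repetition
#' (second standing reading minus mean of the four lying readings),
#' yielding one row per (subject, repetition). Repetitions missing their
#' lying or standing half are skipped with a warning. Features always
#' originate from the lying phase (phase 2).
#'
#' @param raw a `raw_cohort` from [generate_cohort()] or a plain list of
#'   raw instances (as documented there).
#' @param config,artifact_threshold used to extract lying features when an
#'   instance does not carry them yet.
#' @return data.frame: `sub_id`, `test_id`, `symptom_id`, `delta_sys`,
#'   `delta_dia` (mmHg) and the 22 feature columns.
#' @export
build_predictive_dataset <- function(raw, config = feature_config(),
                                     artifact_threshold = 0.05) {
  instances <- if (inherits(raw, "raw_cohort")) raw$instances else raw
  if (inherits(raw, "raw_cohort")) {
    config <- raw$config
    artifact_threshold <- raw$artifact_threshold
  }
  key <- vapply(instances, function(i) {
    paste(i$sub_id, i$phase_id, i$test_id, sep = "/")
  }, character(1))
  lying <- instances[vapply(instances, function(i) i$phase_id == 2L, logical(1))]
  rows <- list()
  for (li in lying) {
    k_std <- paste(li$sub_id, 3, li$test_id, sep = "/")
    j <- match(k_std, key)
    if (is.na(j)) {
      warning(sprintf("subject %s repetition %s: no matching standing instance; skipped",
                      li$sub_id, li$test_id))
      next
    }
    st <- instances[[j]]
    if (length(li$sys_bp) != 4 || length(st$sys_bp) < 2) {
      warning(sprintf("subject %s repetition %s: incomplete BP readings; skipped",
                      li$sub_id, li$test_id))
      next
    }
    feats <- li$features
    if (is.null(feats)) {
      corrected <- preprocess_rr(li$series, artifact_threshold)
      feats <- hrv_features(corrected, config)
    }
    row <- data.frame(
      sub_id = li$sub_id, test_id = li$test_id,
      symptom_id = if (is.null(li$symptom_id)) NA_integer_ else li$symptom_id,
      delta_sys = compute_delta_bp(st$sys_bp[2], li$sys_bp),
      delta_dia = compute_delta_bp(st$dia_bp[2], li$dia_bp))
    row[hrv_feature_names] <- as.list(unname(feats[hrv_feature_names]))
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) stop("no complete lying/standing pairs found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the HRV feature table for every instance of a cohort
#'
#' Preprocesses each instance's RR series (artefact detection + spline
#' correction) and computes the 22-measure battery, caching the vector on
#' the instance.
#'
#' @param cohort a `raw_cohort` (modified copy returned).
#' @return the cohort with all `features` filled; the assembled table is
#'   attached as attribute `"feature_table"` (data.frame with `sub_id`,
#'   `phase_id`, `test_id` and the 22 feature columns).
#' @export
extract_feature_table <- function(cohort) {
  stopifnot(inherits(cohort, "raw_cohort"))
  tab <- list()
  for (i in seq_along(cohort$instances)) {
    inst <- cohort$instances[[i]]
    if (is.null(inst$features)) {
      corrected <- preprocess_rr(inst$series, cohort$artifact_threshold)
      inst$features <- hrv_features(corrected, cohort$config)
      cohort$instances[[i]] <- inst
    }
    row <- data.frame(sub_id = inst$sub_id, phase_id = inst$phase_id,
                      test_id = inst$test_id)
    row[hrv_feature_names] <- as.list(unname(inst$features[hrv_feature_names]))
    tab[[i]] <- row
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  attr(cohort, "feature_table") <- tab
  cohort
}
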