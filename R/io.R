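#' Write a cohort to the package's CSV dialects
#'
#' Three long-format files: `rr.csv` (`sub_id, phase_id, test_id,
#' beat_index, rr_ms`), `bp.csv` (`sub_id, phase_id, test_id,
#' reading_index, sys_mmhg, dia_mmhg`; `reading_index` is 1 for the single
#' sitting reading and 1..4 for lying/standing), and — for synthetic
#' cohorts — a ground-truth sidecar `truth.csv` (`sub_id, test_id,
#' true_delta_sys, true_delta_dia`).
#'
#' @param cohort a `raw_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raw_cohort") ||
              (is.list(cohort) && !is.null(cohort$instances)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rr_rows <- lapply(cohort$instances, function(inst) {
    data.frame(sub_id = inst$sub_id, phase_id = inst$phase_id,
               test_id = inst$test_id,
               beat_index = seq_along(inst$series$rr),
               rr_ms = inst$series$rr)
  })
  bp_rows <- lapply(cohort$instances, function(inst) {
    data.frame(sub_id = inst$sub_id, phase_id = inst$phase_id,
               test_id = inst$test_id,
               reading_index = seq_along(inst$sys_bp),
               sys_mmhg = inst$sys_bp, dia_mmhg = inst$dia_bp)
  })
  paths <- c(rr = file.path(dir, "rr.csv"), bp = file.path(dir, "bp.csv"))
  write.csv(do.call(rbind, rr_rows), paths["rr"], row.names = FALSE)
  write.csv(do.call(rbind, bp_rows), paths["bp"], row.names = FALSE)
  if (!is.null(cohort$truth)) {
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  }
  invisible(paths)
}

check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in required) {
    bad <- which(!is.finite(as.numeric(df[[col]])))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric or missing '%s' at row(s) %s", path, col,
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  df
}

#' Read RR-interval series from the long-format CSV
#'
#' @param path CSV with columns `sub_id, phase_id, test_id, beat_index,
#'   rr_ms`. Schema violations are reported with row numbers.
#' @return list of [rr_series], one per (sub_id, phase_id, test_id).
#' @export
read_rr_csv <- function(path) {
  df <- read.csv(path)
  df <- check_schema(df, c("sub_id", "phase_id", "test_id", "beat_index",
                           "rr_ms"), path)
  df <- df[order(df$sub_id, df$phase_id, df$test_id, df$beat_index), ]
  keys <- unique(df[c("sub_id", "phase_id", "test_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- df$sub_id == k$sub_id & df$phase_id == k$phase_id &
      df$test_id == k$test_id
    rr_series(df$rr_ms[sel], k$sub_id, k$phase_id, k$test_id)
  })
}

#' Read BP measurement tables from the long-format CSV
#'
#' @param path CSV with columns `sub_id, phase_id, test_id,
#'   reading_index, sys_mmhg, dia_mmhg`. BP values must lie in
#'   (40, 260) mmHg.
#' @return data.frame of the readings, ordered by subject/phase/repetition.
#' @export
read_bp_csv <- function(path) {
  df <- read.csv(path)
  df <- check_schema(df, c("sub_id", "phase_id", "test_id", "reading_index",
                           "sys_mmhg", "dia_mmhg"), path)
  bad <- which(df$sys_mmhg <= 40 | df$sys_mmhg >= 260 |
                 df$dia_mmhg <= 40 | df$dia_mmhg >= 260)
  if (length(bad) > 0) {
    stop(sprintf("%s: BP outside (40, 260) mmHg at row(s) %s", path,
                 paste(head(bad, 5), collapse = ", ")))
  }
  df[order(df$sub_id, df$phase_id, df$test_id, df$reading_index), ]
}

#' Assemble a raw cohort from RR and BP CSV files
#'
#' Joins the two long-format files into the same instance structure that
#' [generate_cohort()] produces (without ground truth), ready for
#' [extract_feature_table()] and [build_predictive_dataset()].
#'
#' @param rr_path,bp_path file paths (see [read_rr_csv()],
#'   [read_bp_csv()]).
#' @param config a [feature_config()].
#' @param artifact_threshold artefact filter threshold.
#' @return a `raw_cohort`.
#' @export
read_cohort_csv <- function(rr_path, bp_path, config = feature_config(),
                            artifact_threshold = 0.05) {
  series_list <- read_rr_csv(rr_path)
  bp <- read_bp_csv(bp_path)
  instances <- lapply(series_list, function(s) {
    sel <- bp$sub_id == s$sub_id & bp$phase_id == s$phase_id &
      bp$test_id == s$test_id
    list(sub_id = s$sub_id, phase_id = s$phase_id, test_id = s$test_id,
         symptom_id = NA_integer_,
         sys_bp = bp$sys_mmhg[sel], dia_bp = bp$dia_mmhg[sel],
         series = s, features = NULL)
  })
  subs <- unique(vapply(instances, function(i) i$sub_id, numeric(1)))
  reps <- vapply(instances, function(i) i$test_id, numeric(1))
  structure(list(instances = instances, truth = NULL,
                 n_subjects = length(subs), n_reps = max(reps),
                 model = NULL, model_dia = NULL, seed = NA,
                 config = config, artifact_threshold = artifact_threshold),
            class = "raw_cohort")
}
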