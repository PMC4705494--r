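#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. Either supply `rr_csv` +
#' `bp_csv` to analyse recorded data, or leave them `NULL` to simulate a
#' synthetic cohort with the given protocol parameters.
#'
#' @param rr_csv,bp_csv input CSV paths (see [read_rr_csv()],
#'   [read_bp_csv()]); `NULL` for simulate mode.
#' @param output_dir directory for all artifacts.
#' @param seed base RNG seed (simulation and any derived streams).
#' @param n_subjects,n_reps cohort size in simulate mode; defaults 10 and
#'   4, the reference protocol.
#' @param model,model_dia planted [true_model()]s in simulate mode.
#' @param feature_config a [feature_config()].
#' @param artifact_threshold RR artefact filter threshold; default 0.05.
#' @param max_k largest feature-subset size; default 5.
#' @param error_threshold %CP threshold (mmHg); default 4.5.
#' @param margin FP/FN margin (mmHg); default 5.
#' @param tuning bisquare tuning constant; default 4.685.
#' @param sigma_mode LOSO sigma mode, `"per_fold"` or `"pooled"`.
#' @param features candidate features for the search.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(rr_csv = NULL, bp_csv = NULL,
                            output_dir = tempfile("hrvdrop_run_"),
                            seed = 1L, n_subjects = 10L, n_reps = 4L,
                            model = default_true_model(), model_dia = NULL,
                            feature_config = hrvdrop::feature_config(),
                            artifact_threshold = 0.05,
                            max_k = 5, error_threshold = 4.5, margin = 5,
                            tuning = 4.685,
                            sigma_mode = "per_fold",
                            features = hrv_feature_names) {
  stopifnot(artifact_threshold > 0, error_threshold > 0, margin > 0,
            max_k >= 1)
  structure(list(rr_csv = rr_csv, bp_csv = bp_csv, output_dir = output_dir,
                 seed = as.integer(seed), n_subjects = n_subjects,
                 n_reps = n_reps, model = model, model_dia = model_dia,
                 feature_config = feature_config,
                 artifact_threshold = artifact_threshold, max_k = max_k,
                 error_threshold = error_threshold, margin = margin,
                 tuning = tuning, sigma_mode = sigma_mode,
                 features = features),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be set in a YAML mapping; the
#' planted model is given as `model: {c0: ..., eps_sd: ..., coeffs:
#' {RMSSD: 0.45, ...}}`. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$model)) {
    raw$model <- true_model(raw$model$c0, unlist(raw$model$coeffs),
                            raw$model$eps_sd %||% 0)
  }
  if (!is.null(raw$model_dia)) {
    raw$model_dia <- true_model(raw$model_dia$c0,
                                unlist(raw$model_dia$coeffs),
                                raw$model_dia$eps_sd %||% 0)
  }
  if (!is.null(raw$feature_config)) {
    raw$feature_config <- do.call(feature_config, raw$feature_config)
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate (or read) -> preprocess -> extract features -> build the
#' predictive dataset -> exhaustive LOSO subset search + robust fit ->
#' evaluation report. Deterministic given the seed and configuration.
#'
#' Artifacts written under `config$output_dir`: simulated `rr.csv`,
#' `bp.csv`, `truth.csv` (simulate mode), `features.csv`,
#' `predictive.csv`, `model.json`, `report.json`, `predictions.csv`,
#' `residual_histogram.csv` and a `manifest.json` recording the
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the [bpdrop_fit()] object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$rr_csv)) {
    say(sprintf("simulating cohort: %d subjects x %d repetitions (seed %d)",
                config$n_subjects, config$n_reps, config$seed))
    cohort <- generate_cohort(config$n_subjects, config$n_reps,
                              model = config$model,
                              model_dia = config$model_dia,
                              seed = config$seed,
                              config = config$feature_config,
                              artifact_threshold = config$artifact_threshold,
                              extract_features = "none")
    write_cohort_csv(cohort, config$output_dir)
  } else {
    say(sprintf("reading cohort from %s / %s", config$rr_csv, config$bp_csv))
    cohort <- read_cohort_csv(config$rr_csv, config$bp_csv,
                              config$feature_config,
                              config$artifact_threshold)
  }

  say("extracting HRV features for all instances")
  cohort <- extract_feature_table(cohort)
  feats <- attr(cohort, "feature_table")
  write.csv(feats, file.path(config$output_dir, "features.csv"),
            row.names = FALSE)
  n_missing <- sum(!is.finite(as.matrix(feats[hrv_feature_names])))
  if (n_missing > 0) {
    say(sprintf("%d feature value(s) not computable (recorded as missing)",
                n_missing))
  }

  say("building predictive dataset")
  ds <- build_predictive_dataset(cohort)
  write.csv(ds, file.path(config$output_dir, "predictive.csv"),
            row.names = FALSE)

  say(sprintf("exhaustive LOSO search (max_k = %d)", config$max_k))
  fit <- bpdrop_fit(ds, max_k = config$max_k, features = config$features,
                    error_threshold = config$error_threshold,
                    margin = config$margin, tuning = config$tuning,
                    sigma_mode = config$sigma_mode)

  model_to_json(fit$model, file.path(config$output_dir, "model.json"))
  write_report(fit, config$output_dir)
  manifest <- config
  manifest$model <- if (!is.null(config$model)) {
    list(c0 = config$model$c0, coeffs = as.list(config$model$coeffs),
         eps_sd = config$model$eps_sd)
  }
  manifest$model_dia <- if (!is.null(config$model_dia)) {
    list(c0 = config$model_dia$c0, coeffs = as.list(config$model_dia$coeffs),
         eps_sd = config$model_dia$eps_sd)
  }
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null",
                              force = TRUE),
             file.path(config$output_dir, "manifest.json"))
  say("done")
  invisible(fit)
}
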