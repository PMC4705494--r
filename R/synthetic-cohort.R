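#' Per-subject physiological parameters for the synthetic cohort
#'
#' Describes one synthetic subject: the mean RR interval, the amplitudes
#' and frequencies of two sinusoidal autonomic modulations (one in the LF
#' band, one in the HF band), beat-to-beat white noise, and baseline lying
#' blood pressure with its measurement noise. Together these control the
#' subject's SDNN, LF/HF balance and BP level.
#'
#' @param mu_rr mean RR interval (ms); > 0.
#' @param a_lf,f_lf amplitude (ms) and frequency (Hz) of the low-frequency
#'   modulation; `0.04 <= f_lf < 0.15`.
#' @param a_hf,f_hf amplitude (ms) and frequency (Hz) of the high-frequency
#'   (respiratory) modulation; `0.15 <= f_hf <= 0.4`.
#' @param sigma_rr SD of the white beat-to-beat noise (ms).
#' @param sys_base,dia_base baseline lying systolic/diastolic BP (mmHg).
#' @param sigma_bp SD of BP measurement noise (mmHg).
#' @return object of class `subject_params`.
#' @export
subject_params <- function(mu_rr = 850, a_lf = 15, f_lf = 0.1,
                           a_hf = 15, f_hf = 0.25, sigma_rr = 8,
                           sys_base = 120, dia_base = 75, sigma_bp = 3) {
  if (mu_rr <= 0) stop("mu_rr must be positive")
  if (a_lf < 0 || a_hf < 0 || sigma_rr < 0 || sigma_bp < 0) {
    stop("amplitudes and SDs must be non-negative")
  }
  if (!(f_lf >= 0.04 && f_lf < 0.15)) stop("f_lf must lie in [0.04, 0.15)")
  if (!(f_hf >= 0.15 && f_hf <= 0.4)) stop("f_hf must lie in [0.15, 0.4]")
  if (mu_rr <= a_lf + a_hf) {
    stop("mu_rr must exceed a_lf + a_hf (non-positive intervals possible)")
  }
  structure(list(mu_rr = mu_rr, a_lf = a_lf, f_lf = f_lf,
                 a_hf = a_hf, f_hf = f_hf, sigma_rr = sigma_rr,
                 sys_base = sys_base, dia_base = dia_base,
                 sigma_bp = sigma_bp),
            class = "subject_params")
}

#' Ground-truth linear model linking HRV to the BP drop
#'
#' The synthetic cohort injects a systolic BP change on standing that
#' truly follows `delta_BP = c0 + sum_j c_j * f_j + eps`, where the `f_j`
#' are lying-phase HRV measures and `eps ~ N(0, eps_sd)`. Holding the
#' coefficients lets parameter-recovery and subset-selection tests check
#' the whole pipeline against a known answer.
#'
#' @param c0 intercept (mmHg).
#' @param coeffs named numeric vector; names must be a subset of
#'   [hrv_feature_names].
#' @param eps_sd SD of the Gaussian model noise (mmHg); >= 0.
#' @return object of class `true_model`.
#' @export
true_model <- function(c0, coeffs, eps_sd = 0) {
  coeffs <- unlist(coeffs)
  if (is.null(names(coeffs)) || !all(names(coeffs) %in% hrv_feature_names)) {
    stop("every coefficient must be named after one of the 22 HRV measures")
  }
  if (eps_sd < 0) stop("eps_sd must be non-negative")
  structure(list(c0 = c0, coeffs = coeffs, eps_sd = eps_sd),
            class = "true_model")
}

#' Default ground-truth model for simulations
#'
#' A physiologically plausible systolic-drop model: larger drops with
#' depressed short-term variability and raised determinism, around a
#' baseline drop of -26 mmHg at zero features, with 3 mmHg model noise.
#'
#' @return a [true_model()].
#' @export
default_true_model <- function() {
  true_model(c0 = -26,
             coeffs = c(RMSSD = 0.45, HF = -0.01, RPDET = 0.3),
             eps_sd = 3)
}

#' Draw plausible per-subject parameters for a synthetic cohort
#'
#' Subject heterogeneity is sampled uniformly over ranges plausible for
#' resting adults while keeping generated (artefact-free) series mostly
#' below the 5 percent artefact-filter deviation: mean RR 750--950 ms,
#' modulation amplitudes 10--20 ms (LF, around 0.1 Hz) and 10--20 ms
#' (HF, 0.2--0.3 Hz), beat-to-beat noise 5--12 ms, systolic baseline
#' 105--135 mmHg, diastolic 65--85 mmHg, and the 3 mmHg nominal cuff
#' error.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @return list of [subject_params()] of length `n_subjects`.
#' @export
sample_cohort_params <- function(n_subjects, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      subject_params(
        mu_rr    = runif(1, 750, 950),
        a_lf     = runif(1, 10, 20),
        f_lf     = runif(1, 0.08, 0.12),
        a_hf     = runif(1, 10, 20),
        f_hf     = runif(1, 0.20, 0.30),
        sigma_rr = runif(1, 5, 12),
        sys_base = runif(1, 105, 135),
        dia_base = runif(1, 65, 85),
        sigma_bp = 3
      )
    })
  })
}

#' Generate one synthetic RR-interval series
#'
#' Beat-to-beat model: `RR_i = mu_rr + a_lf sin(2 pi f_lf t_i) +
#' a_hf sin(2 pi f_hf t_i) + sigma_rr w_i` with `w_i` standard normal and
#' `t_i` the cumulative beat time at which interval i begins — the
#' modulation is evaluated on the irregular beat grid, the way real
#' autonomic modulation acts. Beats are appended until the cumulative time
#' covers `duration`.
#'
#' @param params a [subject_params()].
#' @param duration recording length (s); > 0.
#' @param seed RNG seed; the series is reproducible per seed.
#' @param sub_id,phase_id,test_id identity carried on the result.
#' @return an [rr_series].
#' @details Parameter sets able to produce non-positive intervals
#'   (`mu_rr <= a_lf + a_hf + 5 sigma_rr`) are rejected.
#' @examples
#' s <- generate_rr_series(subject_params(a_lf = 0, a_hf = 0, sigma_rr = 0,
#'                                        mu_rr = 800), 300, seed = 1)
#' length(s$rr)  # 375 beats of exactly 800 ms
#' @export
generate_rr_series <- function(params, duration, seed,
                               sub_id = NA_integer_, phase_id = NA_integer_,
                               test_id = NA_integer_) {
  stopifnot(inherits(params, "subject_params"), duration > 0)
  if (params$mu_rr <= params$a_lf + params$a_hf + 5 * params$sigma_rr) {
    stop("parameters can produce RR <= 0: require mu_rr > a_lf + a_hf + 5*sigma_rr")
  }
  with_seed(seed, {
    # upper bound on beats needed, then trim to the first covering duration
    n_max <- ceiling(1000 * duration /
                       (params$mu_rr - params$a_lf - params$a_hf -
                          5 * params$sigma_rr)) + 10L
    rr <- numeric(n_max)
    t <- 0
    n <- 0L
    w <- rnorm(n_max)
    while (t < duration) {
      n <- n + 1L
      if (n > n_max) {  # extremely unlikely; extend the noise stream
        w <- c(w, rnorm(n_max))
        rr <- c(rr, numeric(n_max))
        n_max <- 2L * n_max
      }
      rr_i <- params$mu_rr +
        params$a_lf * sin(2 * pi * params$f_lf * t) +
        params$a_hf * sin(2 * pi * params$f_hf * t) +
        params$sigma_rr * w[n]
      rr[n] <- rr_i
      t <- t + rr_i / 1000
    }
    rr_series(rr[seq_len(n)], sub_id, phase_id, test_id)
  })
}

#' Generate a protocol-faithful synthetic cohort
#'
#' Emulates the three-phase orthostatic protocol: per subject, one sitting
#' instance (2-min RR, 1 systolic + 1 diastolic BP) and `n_reps` lying and
#' standing instances (5-min RR each; 4 BP readings each). Standing BP
#' readings are generated as `mean(lying BPs) + delta + N(0, sigma_bp)`,
#' where the realised drop `delta = c0 + sum_j c_j f_j(lying RR) +
#' N(0, eps_sd)` is computed from the subject's artefact-corrected
#' lying-phase HRV features, so the cohort's drop truly follows the
#' planted linear model. The realised drops are stored as ground truth.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_reps lying/standing repetitions per subject (>= 1); 4 in the
#'   reference protocol.
#' @param subject_params list of [subject_params()], one per subject;
#'   defaults to [sample_cohort_params()].
#' @param model a [true_model()] for the systolic drop.
#' @param model_dia optional [true_model()] for the diastolic drop;
#'   when `NULL` (default) standing diastolic BP stays at baseline.
#' @param seed base RNG seed; per-(subject, phase, repetition) streams are
#'   derived deterministically, so enlarging the cohort does not reshuffle
#'   existing subjects.
#' @param config [feature_config()] used for the lying-phase features.
#' @param artifact_threshold artefact filter threshold applied before
#'   feature extraction (see [detect_artifacts()]).
#' @param extract_features `"lying"` (default) computes features only for
#'   lying series (those enter the planted model); `"all"` fills every
#'   instance; `"none"` leaves extraction to [extract_feature_table()].
#' @return object of class `raw_cohort`: list with `instances` (list of
#'   raw instances: `sub_id`, `phase_id`, `test_id`, `symptom_id`,
#'   `sys_bp`, `dia_bp`, `series`, `features`), `truth` (data.frame
#'   `sub_id`, `test_id`, `true_delta_sys`, `true_delta_dia`), plus the
#'   generation settings.
#' @examples
#' \donttest{
#' coh <- generate_cohort(3, 2, seed = 7)
#' length(coh$instances)  # 3 * (1 + 2 + 2)
#' }
#' @export
generate_cohort <- function(n_subjects, n_reps = 4,
                            subject_params = NULL,
                            model = default_true_model(),
                            model_dia = NULL,
                            seed = 1L,
                            config = feature_config(),
                            artifact_threshold = 0.05,
                            extract_features = c("lying", "all", "none")) {
  extract_features <- match.arg(extract_features)
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (n_reps < 1) stop("need at least 1 repetition")
  stopifnot(inherits(model, "true_model"))
  if (is.null(subject_params)) {
    subject_params <- sample_cohort_params(n_subjects, seed = seed)
  }
  if (length(subject_params) != n_subjects) {
    stop(sprintf("subject_params has length %d but n_subjects is %d",
                 length(subject_params), n_subjects))
  }

  features_of <- function(series) {
    corrected <- preprocess_rr(series, artifact_threshold)
    hrv_features(corrected, config)
  }
  planted_delta <- function(feats, tm, eps) {
    tm$c0 + sum(tm$coeffs * feats[names(tm$coeffs)]) + eps
  }

  instances <- list()
  truth <- NULL
  for (s in seq_len(n_subjects)) {
    p <- subject_params[[s]]
    # phase 1: sitting
    sit_series <- generate_rr_series(p, 120, derive_seed(seed, s, 1, 0),
                                     sub_id = s, phase_id = 1, test_id = 0)
    sit_bp <- with_seed(derive_seed(seed, s, 1, 0, salt = 1), {
      c(sys = p$sys_base + rnorm(1, 0, p$sigma_bp),
        dia = p$dia_base + rnorm(1, 0, p$sigma_bp))
    })
    instances[[length(instances) + 1L]] <- list(
      sub_id = s, phase_id = 1L, test_id = 0L, symptom_id = 0L,
      sys_bp = unname(sit_bp["sys"]), dia_bp = unname(sit_bp["dia"]),
      series = sit_series,
      features = if (extract_features == "all") features_of(sit_series) else NULL)

    for (r in seq_len(n_reps)) {
      lie_series <- generate_rr_series(p, 300, derive_seed(seed, s, 2, r),
                                       sub_id = s, phase_id = 2, test_id = r)
      lie_bp <- with_seed(derive_seed(seed, s, 2, r, salt = 1), {
        list(sys = p$sys_base + rnorm(4, 0, p$sigma_bp),
             dia = p$dia_base + rnorm(4, 0, p$sigma_bp))
      })
      lie_feats <- if (extract_features %in% c("lying", "all")) {
        features_of(lie_series)
      } else NULL
      feats_for_model <- if (is.null(lie_feats)) features_of(lie_series) else lie_feats

      std_series <- generate_rr_series(p, 300, derive_seed(seed, s, 3, r),
                                       sub_id = s, phase_id = 3, test_id = r)
      noise <- with_seed(derive_seed(seed, s, 3, r, salt = 1), {
        list(eps_sys = rnorm(1, 0, model$eps_sd),
             eps_dia = if (!is.null(model_dia)) rnorm(1, 0, model_dia$eps_sd) else 0,
             bp_sys = rnorm(4, 0, p$sigma_bp),
             bp_dia = rnorm(4, 0, p$sigma_bp))
      })
      d_sys <- planted_delta(feats_for_model, model, noise$eps_sys)
      d_dia <- if (!is.null(model_dia)) {
        planted_delta(feats_for_model, model_dia, noise$eps_dia)
      } else 0
      std_sys <- mean(lie_bp$sys) + d_sys + noise$bp_sys
      std_dia <- mean(lie_bp$dia) + d_dia + noise$bp_dia
      symptom <- if (d_sys <= -20) 2L else if (d_sys <= -10) 1L else 0L

      instances[[length(instances) + 1L]] <- list(
        sub_id = s, phase_id = 2L, test_id = r, symptom_id = symptom,
        sys_bp = lie_bp$sys, dia_bp = lie_bp$dia,
        series = lie_series, features = lie_feats)
      instances[[length(instances) + 1L]] <- list(
        sub_id = s, phase_id = 3L, test_id = r, symptom_id = symptom,
        sys_bp = std_sys, dia_bp = std_dia,
        series = std_series,
        features = if (extract_features == "all") features_of(std_series) else NULL)
      truth <- rbind(truth, data.frame(
        sub_id = s, test_id = r,
        true_delta_sys = d_sys, true_delta_dia = d_dia))
    }
  }
  structure(list(instances = instances, truth = truth,
                 n_subjects = n_subjects, n_reps = n_reps,
                 model = model, model_dia = model_dia, seed = seed,
                 config = config, artifact_threshold = artifact_threshold),
            class = "raw_cohort")
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic orthostatic cohort: %d subjects x (1 sitting + %d lying + %d standing) = %d instances\n",
    x$n_subjects, x$n_reps, x$n_reps, length(x$instances)))
  cat(sprintf("  planted systolic model: c0 = %.2f, features: %s (eps_sd = %.2f mmHg)\n",
              x$model$c0, paste(names(x$model$coeffs), collapse = ", "),
              x$model$eps_sd))
  invisible(x)
}
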