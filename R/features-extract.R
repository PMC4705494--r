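#' Names of the 22 HRV measures, in standard battery order
#'
#' Time domain (MeanRR, STDNN, RMSSD, NN50, pNN50, HRVtri, TINN),
#' frequency domain (LF, HF, LFHF), and nonlinear measures (SD1, SD2,
#' ApEn, SampEn, D2, DFA1, DFA2, RPLmean, RPLmax, RPREC, RPDET, RPShan).
#'
#' @format character vector of length 22.
#' @export
hrv_feature_names <- c(
  "MeanRR", "STDNN", "RMSSD", "NN50", "pNN50", "HRVtri", "TINN",
  "LF", "HF", "LFHF",
  "SD1", "SD2", "ApEn", "SampEn", "D2", "DFA1", "DFA2",
  "RPLmean", "RPLmax", "RPREC", "RPDET", "RPShan"
)

#' Configuration for HRV feature extraction
#'
#' Collects every tunable parameter of the 22-measure battery with the
#' conventional defaults of standard HRV analysis software. All overridable.
#'
#' @param resample_hz tachogram resampling rate (Hz) for spectral analysis.
#' @param ar_order Burg autoregressive model order.
#' @param lf_band,hf_band spectral band edges (Hz); must be ordered and
#'   disjoint.
#' @param hist_bin RR histogram bin width (s) for HRVtri/TINN.
#' @param entropy_m,entropy_r_factor template length and tolerance factor
#'   (fraction of STDNN) for ApEn/SampEn.
#' @param rqa_m,rqa_tau,rqa_r_factor,rqa_lmin recurrence-plot embedding
#'   dimension, delay, radius factor (multiple of `sqrt(m) * STDNN`) and
#'   minimum diagonal line length.
#' @param dfa_short,dfa_long DFA box-size ranges (beats).
#' @param d2_m embedding dimension for the correlation dimension.
#' @return object of class `feature_config` (a named list).
#' @export
feature_config <- function(resample_hz = 4, ar_order = 16,
                           lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                           hist_bin = 1 / 128,
                           entropy_m = 2L, entropy_r_factor = 0.2,
                           rqa_m = 10L, rqa_tau = 1L, rqa_r_factor = 1.0,
                           rqa_lmin = 2L,
                           dfa_short = c(4, 16), dfa_long = c(16, 64),
                           d2_m = 10L) {
  stopifnot(resample_hz > 0, ar_order >= 1,
            lf_band[1] < lf_band[2], hf_band[1] < hf_band[2],
            lf_band[2] <= hf_band[1] + 1e-12,
            hist_bin > 0, entropy_m >= 1, entropy_r_factor >= 0,
            rqa_m >= 1, rqa_tau >= 1, rqa_lmin >= 2, d2_m >= 1)
  structure(list(
    resample_hz = resample_hz, ar_order = as.integer(ar_order),
    lf_band = lf_band, hf_band = hf_band, hist_bin = hist_bin,
    entropy_m = as.integer(entropy_m), entropy_r_factor = entropy_r_factor,
    rqa_m = as.integer(rqa_m), rqa_tau = as.integer(rqa_tau),
    rqa_r_factor = rqa_r_factor, rqa_lmin = as.integer(rqa_lmin),
    dfa_short = dfa_short, dfa_long = dfa_long, d2_m = as.integer(d2_m)
  ), class = "feature_config")
}

#' Extract the full 22-measure HRV feature vector
#'
#' Runs the complete battery on a (corrected) RR series and assembles the
#' measures in standard order. Measures that cannot be computed on the
#' given series (too short, degenerate, no scaling region) are returned as
#' `NA` and the reason recorded in the `"missing_reasons"` attribute —
#' never silently zero.
#'
#' @param series an [rr_series] (or numeric RR vector in ms).
#' @param config a [feature_config()].
#' @return named numeric vector of length 22 (names [hrv_feature_names]),
#'   with attribute `missing_reasons` (named character).
#' @examples
#' s <- rr_series(800 + 30 * sin(2 * pi * 0.25 * cumsum(rep(0.8, 400))))
#' f <- hrv_features(s)
#' f[c("MeanRR", "HF", "LFHF")]
#' @export
hrv_features <- function(series, config = feature_config()) {
  series <- as_rr_series(series)
  out <- setNames(rep(NA_real_, length(hrv_feature_names)), hrv_feature_names)
  reasons <- character(0)
  put <- function(vals) {
    for (nm in names(vals)) out[nm] <<- as.numeric(vals[[nm]])
  }
  try_block <- function(nms, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      for (nm in nms) reasons[nm] <<- res
    } else {
      put(res)
      miss <- nms[vapply(nms, function(nm) is.na(out[nm]), logical(1))]
      for (nm in miss) reasons[nm] <<- "not computable on this series"
    }
  }
  rr <- series$rr
  try_block(c("MeanRR", "STDNN", "RMSSD", "NN50", "pNN50"),
            hrv_time_domain(rr))
  try_block(c("HRVtri", "TINN"), hrv_triangular(rr, config$hist_bin))
  try_block(c("LF", "HF", "LFHF"),
            hrv_spectral(series, config$resample_hz, config$ar_order,
                         config$lf_band, config$hf_band))
  try_block(c("SD1", "SD2"), hrv_poincare(rr))
  try_block(c("ApEn", "SampEn"),
            hrv_entropy(rr, config$entropy_m, r_factor = config$entropy_r_factor))
  try_block("D2", list(D2 = hrv_corr_dim(rr, config$d2_m)))
  try_block(c("DFA1", "DFA2"),
            hrv_dfa(rr, config$dfa_short, config$dfa_long))
  try_block(c("RPLmean", "RPLmax", "RPREC", "RPDET", "RPShan"),
            hrv_rqa(rr, config$rqa_m, config$rqa_tau, config$rqa_r_factor,
                    config$rqa_lmin))
  attr(out, "missing_reasons") <- reasons
  out
}
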