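#' Frequency-domain HRV measures via Burg autoregressive spectra
#'
#' The RR tachogram (interval value against beat time) is mean-centred,
#' resampled at a uniform rate by cubic-spline interpolation, and fitted
#' with an autoregressive model by Burg's method. Absolute band powers are
#' obtained by integrating the one-sided AR spectral density over the
#' low-frequency (LF) and high-frequency (HF) bands.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param resample_hz uniform resampling rate of the tachogram (Hz);
#'   default 4.
#' @param ar_order Burg model order; default 16.
#' @param lf_band,hf_band numeric length-2 band edges in Hz; defaults
#'   0.04--0.15 (LF) and 0.15--0.40 (HF).
#' @return named list: `LF`, `HF` (ms^2) and `LFHF` (their ratio; `NA` if
#'   the HF power is zero).
#' @details The series must span at least 2 minutes: band resolution at
#'   0.04 Hz needs that much data. Powers are in ms^2 because the tachogram
#'   is in ms. A sinusoidal modulation of amplitude `A` inside a band
#'   contributes close to `A^2 / 2` to that band's power.
#' @export
hrv_spectral <- function(rr, resample_hz = 4, ar_order = 16,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  series <- as_rr_series(rr)
  rr <- series$rr
  t <- series$t
  if (sum(rr) / 1000 < 120) stop("series must span at least 2 minutes")
  if (lf_band[1] >= lf_band[2] || hf_band[1] >= hf_band[2] ||
      lf_band[2] > hf_band[1] + 1e-12) {
    stop("bands must be ordered and disjoint")
  }
  fs <- resample_hz
  x <- rr - mean(rr)
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  xs <- stats::splinefun(t, x, method = "fmm")(grid)
  xs <- xs - mean(xs)
  if (stats::var(xs) < 1e-12) {
    return(list(LF = 0, HF = 0, LFHF = NA_real_))
  }
  fit <- stats::ar.burg(xs, aic = FALSE, order.max = ar_order, demean = TRUE)
  a <- fit$ar
  sig2 <- fit$var.pred
  nf <- 4096L
  f <- seq(0, fs / 2, length.out = nf + 1L)
  # one-sided AR PSD: 2 * (sig2/fs) / |1 - sum a_k exp(-i 2 pi f k / fs)|^2
  ek <- exp(-2i * pi * outer(f / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(ek %*% a))^2
  psd <- 2 * (sig2 / fs) / denom
  band_power <- function(band) {
    m <- f >= band[1] & f <= band[2]
    if (sum(m) < 2) return(0)
    fi <- f[m]; pi_ <- psd[m]
    sum(diff(fi) * (head(pi_, -1) + pi_[-1]) / 2)  # trapezoid
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  list(LF = lf, HF = hf, LFHF = if (hf > 0) lf / hf else NA_real_)
}
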