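#' Time-domain HRV measures
#'
#' The five classic time-domain statistics of an RR series: mean interval,
#' overall variability (STDNN, the sample SD), short-term variability
#' (RMSSD), and the count/percentage of successive-interval differences
#' exceeding 50 ms.
#'
#' `pNN50` uses the number of successive pairs (`N - 1`) as denominator,
#' the dominant convention in the HRV guidelines.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @return named list: `MeanRR`, `STDNN` (ms), `RMSSD` (ms), `NN50`
#'   (count), `pNN50` (percent).
#' @examples
#' hrv_time_domain(c(800, 860, 865, 920))
#' @export
hrv_time_domain <- function(rr) {
  rr <- as_rr_series(rr)$rr
  n <- length(rr)
  if (n < 2) stop("need at least 2 intervals")
  d <- diff(rr)
  nn50 <- sum(abs(d) > 50)
  list(
    MeanRR = mean(rr),
    STDNN  = stats::sd(rr),
    RMSSD  = sqrt(mean(d^2)),
    NN50   = nn50,
    pNN50  = 100 * nn50 / (n - 1)
  )
}

#' Geometric HRV measures from the RR histogram
#'
#' `HRVtri`, the HRV triangular index, is the total number of intervals
#' divided by the height of the modal histogram bin. `TINN` is the baseline
#' width (ms) of the best least-squares triangular fit to the histogram:
#' among all triangles rising linearly from zero at bin `N` to the modal
#' height at the modal bin `M` and falling to zero at bin `P`, the pair
#' `(N, P)` minimising the squared error against the bin counts is chosen
#' (tie-break: smallest width), and `TINN = (P - N) * bin width`.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param hist_bin histogram bin width in seconds; default 1/128 s, the
#'   guideline sampling convention.
#' @return named list: `HRVtri` (unitless), `TINN` (ms).
#' @export
hrv_triangular <- function(rr, hist_bin = 1 / 128) {
  rr <- as_rr_series(rr)$rr
  n <- length(rr)
  if (n < 20) stop("need at least 20 intervals for a meaningful histogram")
  bw <- hist_bin * 1000  # ms
  idx <- floor(rr / bw)  # bin index of each interval (edges at multiples of bw)
  lo <- min(idx); hi <- max(idx)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  ymax <- max(counts)
  hrv_tri <- n / ymax
  if (sum(counts > 0) == 1L) {
    warning("degenerate RR histogram: all intervals in one bin")
    return(list(HRVtri = hrv_tri, TINN = 0))
  }
  # pad with empty bins so the triangle base may extend beyond the support
  nb <- length(counts)
  pad <- nb
  D <- c(numeric(pad), counts, numeric(pad))
  M <- pad + which.max(counts)         # modal bin (first maximum)
  Y <- D[M]
  total <- length(D)
  best <- c(err = Inf, N = NA, P = NA)
  for (N in seq_len(M - 1)) {
    up <- numeric(total)
    ramp <- seq(N, M)
    up[ramp] <- Y * (ramp - N) / (M - N)
    err_left <- sum((D[1:M] - up[1:M])^2)
    for (P in seq(M + 1, total)) {
      down <- numeric(total - M)
      ramp2 <- seq(M + 1, P)
      down[ramp2 - M] <- Y * (P - ramp2) / (P - M)
      err <- err_left + sum((D[(M + 1):total] - down)^2)
      w <- P - N
      if (err < best["err"] - 1e-12 ||
          (abs(err - best["err"]) <= 1e-12 && w < best["P"] - best["N"])) {
        best <- c(err = err, N = N, P = P)
      }
    }
  }
  list(HRVtri = hrv_tri, TINN = (best[["P"]] - best[["N"]]) * bw)
}

#' Poincare-plot dispersion measures
#'
#' `SD1` is the dispersion of the lag-1 return map perpendicular to the
#' identity line — algebraically the SD of successive differences divided
#' by sqrt(2) — and indexes short-term variability. `SD2`, the dispersion
#' along the identity line, is obtained from the identity
#' `SD1^2 + SD2^2 = 2 * STDNN^2`.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @return named list: `SD1`, `SD2` (ms).
#' @export
hrv_poincare <- function(rr) {
  rr <- as_rr_series(rr)$rr
  if (length(rr) < 3) stop("need at least 3 intervals")
  sd1 <- stats::sd(diff(rr)) / sqrt(2)
  sdnn <- stats::sd(rr)
  sd2 <- sqrt(max(0, 2 * sdnn^2 - sd1^2))
  list(SD1 = sd1, SD2 = sd2)
}
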