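# Time-delay embedding: row i is (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}).
embed_delay <- function(x, m, tau = 1L) {
  n <- length(x) - (m - 1L) * tau
  if (n < 2) stop("series too short for this embedding")
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, "+")
  matrix(x[idx], nrow = n, ncol = m)
}

#' Approximate and sample entropy
#'
#' Regularity statistics counting template matches of length `m` within a
#' Chebyshev (maximum-norm) tolerance `r`. Approximate entropy (ApEn)
#' includes self-matches and averages the log of per-template match
#' frequencies; sample entropy (SampEn) excludes self-matches and takes
#' the log-ratio of total match counts at lengths `m` and `m + 1`, making
#' it less biased on short series. Low values mean a more regular,
#' predictable rhythm.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param m template length; default 2.
#' @param r tolerance in ms; default `r_factor * STDNN`.
#' @param r_factor tolerance as a fraction of the series SD; default 0.2.
#' @return named list: `ApEn`, `SampEn` (`SampEn` is `NA` when no template
#'   pair matches at length `m + 1`).
#' @export
hrv_entropy <- function(rr, m = 2L, r = NULL, r_factor = 0.2) {
  x <- as_rr_series(rr)$rr
  n <- length(x)
  if (n < 50) stop("need at least 50 intervals")
  if (is.null(r)) r <- r_factor * stats::sd(x)

  # frequency of Chebyshev matches per template, self-matches included
  phi <- function(mm) {
    emb <- embed_delay(x, mm)
    nt <- nrow(emb)
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      d <- abs(emb[, 1] - emb[i, 1])
      for (k in seq_len(mm)[-1]) d <- pmax(d, abs(emb[, k] - emb[i, k]))
      cnt[i] <- sum(d <= r)
    }
    mean(log(cnt / nt))
  }
  apen <- phi(m) - phi(m + 1L)

  # Richman-Moorman counts: N - m templates at both lengths, i < j
  nt <- n - m
  embA <- embed_delay(x, m + 1L)[seq_len(nt), , drop = FALSE]
  A <- 0; B <- 0
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    d <- abs(embA[js, 1] - embA[i, 1])
    for (k in seq_len(m)[-1]) d <- pmax(d, abs(embA[js, k] - embA[i, k]))
    B <- B + sum(d <= r)
    d <- pmax(d, abs(embA[js, m + 1L] - embA[i, m + 1L]))
    A <- A + sum(d <= r)
  }
  sampen <- if (B > 0 && A > 0) -log(A / B) else NA_real_
  list(ApEn = apen, SampEn = sampen)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Embeds the series with delay 1 in `m` dimensions, computes the
#' correlation sum C(r) — the fraction of embedded point pairs within
#' Euclidean distance r — and estimates D2 as the slope of log C(r)
#' against log r over a scaling region. The scaling region is selected
#' deterministically as the radii where C(r) lies in [0.01, 0.3]: enough
#' pairs for a stable estimate, below the saturation shoulder.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param m embedding dimension; default 10.
#' @param n_radii number of log-spaced radii scanned; default 40.
#' @return `D2` estimate, or `NA` when no scaling region exists.
#' @export
hrv_corr_dim <- function(rr, m = 10L, n_radii = 40L) {
  x <- as_rr_series(rr)$rr
  if (length(x) < 200) stop("need at least 200 intervals")
  emb <- embed_delay(x, m)
  d <- as.numeric(stats::dist(emb))
  d <- d[d > 0]
  if (length(d) == 0) return(NA_real_)
  radii <- exp(seq(log(stats::quantile(d, 0.001)), log(max(d)),
                   length.out = n_radii))
  cr <- vapply(radii, function(r) mean(d <= r), numeric(1))
  keep <- cr >= 0.01 & cr <= 0.3
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log(cr[keep]) ~ log(radii[keep]))
  unname(coef(fit)[2])
}

#' Detrended fluctuation analysis scaling exponents
#'
#' The mean-centred series is integrated into a profile, split into
#' non-overlapping boxes of size s, linearly detrended per box, and the
#' root-mean-square fluctuation F(s) computed. `DFA1` is the log-log slope
#' of F(s) over short boxes (default 4--16 beats), `DFA2` over long boxes
#' (default 16--64). White noise gives an exponent near 0.5, a random walk
#' near 1.5; healthy RR series typically sit near 1.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param short_range,long_range integer length-2 box-size ranges.
#' @return named list: `DFA1`, `DFA2` (`DFA2` is `NA` below 300 beats).
#' @export
hrv_dfa <- function(rr, short_range = c(4, 16), long_range = c(16, 64)) {
  x <- as_rr_series(rr)$rr
  n <- length(x)
  if (n < 100) stop("need at least 100 intervals")
  y <- cumsum(x - mean(x))

  fluct <- function(s) {
    k <- n %/% s
    mat <- matrix(y[seq_len(k * s)], nrow = s)
    tt <- seq_len(s)
    # residual-maker for a linear fit in each box
    Tm <- cbind(1, tt)
    res <- mat - Tm %*% solve(crossprod(Tm), crossprod(Tm, mat))
    sqrt(mean(res^2))
  }
  slope_over <- function(range) {
    sizes <- seq(range[1], range[2])
    sizes <- sizes[sizes >= 2 & n %/% sizes >= 2]
    fs <- vapply(sizes, fluct, numeric(1))
    ok <- fs > 0
    if (sum(ok) < 3) return(NA_real_)
    unname(coef(stats::lm(log(fs[ok]) ~ log(sizes[ok])))[2])
  }
  dfa1 <- slope_over(short_range)
  dfa2 <- if (n >= 300) slope_over(long_range) else NA_real_
  list(DFA1 = dfa1, DFA2 = dfa2)
}

#' Recurrence quantification analysis
#'
#' Embeds the series (delay `tau`, dimension `m`), thresholds the pairwise
#' Euclidean distance matrix at `r = r_factor * sqrt(m) * STDNN` and
#' summarises the diagonal-line structure of the resulting recurrence
#' plot. Deterministic dynamics place recurrent points on long diagonals;
#' noise scatters them.
#'
#' @param rr numeric RR intervals (ms) or an [rr_series].
#' @param m embedding dimension; default 10.
#' @param tau embedding delay; default 1.
#' @param r_factor recurrence radius as a multiple of `sqrt(m) * STDNN`;
#'   default 1.
#' @param lmin minimum diagonal line length; default 2.
#' @return named list: `RPLmean`, `RPLmax` (beats), `RPREC`, `RPDET`
#'   (percent), `RPShan` (nats). When there are no recurrent points,
#'   `RPREC` is 0 and the line statistics are `NA`.
#' @details `RPREC` is the percentage of recurrent points among all
#'   ordered pairs excluding the main diagonal; `RPDET` the percentage of
#'   recurrent points lying on diagonal lines of length at least `lmin`;
#'   `RPShan` the Shannon entropy (natural log) of the distribution of
#'   diagonal line lengths.
#' @export
hrv_rqa <- function(rr, m = 10L, tau = 1L, r_factor = 1.0, lmin = 2L) {
  x <- as_rr_series(rr)$rr
  n <- length(x)
  if (n < m * tau + 50) stop("series too short for this embedding")
  r <- r_factor * sqrt(m) * stats::sd(x)
  emb <- embed_delay(x, m, tau)
  M <- nrow(emb)
  R <- as.matrix(stats::dist(emb)) <= r
  n_rec_off <- sum(R) - M            # recurrent ordered pairs, diagonal excluded
  rec <- 100 * n_rec_off / (M^2 - M)
  if (n_rec_off == 0) {
    return(list(RPLmean = NA_real_, RPLmax = NA_real_, RPREC = 0,
                RPDET = NA_real_, RPShan = NA_real_))
  }
  # diagonal line lengths from the upper triangle
  lens <- integer(0)
  for (k in seq_len(M - 1L)) {
    v <- R[cbind(seq_len(M - k), seq_len(M - k) + k)]
    runs <- rle(v)
    lens <- c(lens, runs$lengths[runs$values])
  }
  on_lines <- sum(lens[lens >= lmin])
  det <- 100 * (2 * on_lines) / n_rec_off
  dl <- lens[lens >= lmin]
  if (length(dl) == 0) {
    return(list(RPLmean = NA_real_, RPLmax = NA_real_, RPREC = rec,
                RPDET = det, RPShan = NA_real_))
  }
  pl <- tabulate(dl)
  pl <- pl[pl > 0] / length(dl)
  list(
    RPLmean = mean(dl),
    RPLmax  = max(dl),
    RPREC   = rec,
    RPDET   = det,
    RPShan  = -sum(pl * log(pl))
  )
}
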