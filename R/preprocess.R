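#' Detect artefactual RR intervals
#'
#' Flags beats whose RR interval deviates from the median of its nearest
#' unflagged neighbours by more than a relative threshold. This reproduces
#' the behaviour of the local-median artefact filters used by standard HRV
#' analysis software: ectopic beats and missed/false detections show up as
#' single intervals far from the local beat-to-beat trend.
#'
#' Flags are assigned in one left-to-right pass: when beat `i` is examined,
#' beats already flagged to its left are excluded from its reference window,
#' while beats to its right (not yet examined) are all candidates. The
#' window holds the 5 nearest unflagged neighbours of `i` (ties broken
#' towards the left neighbour).
#'
#' @param series an [rr_series] (or numeric vector of RR in ms).
#' @param threshold relative deviation above which a beat is flagged;
#'   default 0.05 (5 percent).
#' @return logical vector, one flag per beat.
#' @examples
#' detect_artifacts(c(800, 800, 800, 1200, 800, 800))
#' @seealso [correct_artifacts()], [preprocess_rr()]
#' @export
detect_artifacts <- function(series, threshold = 0.05) {
  series <- as_rr_series(series)
  rr <- series$rr
  n <- length(rr)
  if (n < 5) stop("series too short to form a local window (need >= 5 beats)")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)")
  }
  flags <- logical(n)
  for (i in seq_len(n)) {
    m <- local_median_ref(rr, flags, i)
    if (abs(rr[i] - m) / m > threshold) flags[i] <- TRUE
  }
  flags
}

# Median of the (up to) 5 nearest neighbours of beat i not excluded by
# `flags`; ties between equidistant neighbours favour the left one.
local_median_ref <- function(rr, flags, i) {
  n <- length(rr)
  nbr <- numeric(0)
  d <- 1L
  while (length(nbr) < 5L && (i - d >= 1L || i + d <= n)) {
    j <- i - d
    if (j >= 1L && !flags[j]) nbr <- c(nbr, rr[j])
    j <- i + d
    if (length(nbr) < 5L && j <= n && !flags[j]) nbr <- c(nbr, rr[j])
    d <- d + 1L
  }
  stats::median(nbr)
}

#' Correct flagged RR intervals by cubic-spline interpolation
#'
#' Replaces flagged RR values with a cubic spline fitted through the
#' unflagged (beat index, RR) pairs, evaluated at the flagged beat
#' indices, then rebuilds the cumulative beat times from the corrected
#' intervals. Interpolation runs over the beat index rather than the beat
#' time because the artefact itself corrupts the time axis (a spurious
#' 2000 ms interval shifts every later beat time); the index is the only
#' ordinate the artefact leaves intact. Interpolation (rather than
#' deletion) keeps the beat count and time axis consistent for the
#' spectral and nonlinear analyses downstream.
#'
#' @param series an [rr_series].
#' @param mask logical vector from [detect_artifacts()], one entry per beat.
#' @return corrected [rr_series] of the same length.
#' @details More than 5 percent of beats flagged raises a warning (the
#'   filter is meant for sparse artefacts); more than 20 percent is an
#'   error, since a spline through so few anchors is no longer a
#'   correction.
#' @export
correct_artifacts <- function(series, mask) {
  series <- as_rr_series(series)
  rr <- series$rr
  n <- length(rr)
  if (length(mask) != n) stop("mask length must equal series length")
  mask <- as.logical(mask)
  if (all(mask)) stop("all beats flagged; nothing to interpolate from")
  if (!any(mask)) return(series)
  frac <- mean(mask)
  if (frac > 0.20) {
    stop(sprintf("%.1f%% of beats flagged; exceeds the 20%% correction limit",
                 100 * frac))
  }
  if (frac > 0.05) {
    warning(sprintf("%.1f%% of beats flagged; exceeds the 5%% filter ceiling",
                    100 * frac))
  }
  idx <- seq_along(rr)
  f <- stats::splinefun(idx[!mask], rr[!mask], method = "fmm")
  rr[mask] <- f(idx[mask])
  if (any(rr <= 0)) stop("spline correction produced non-positive intervals")
  rr_series(rr, series$sub_id, series$phase_id, series$test_id)
}

#' Detect and correct RR artefacts in one step
#'
#' Repeats detection and correction until the series is a fixpoint of the
#' filter: a freshly corrected beat can occasionally still sit just
#' outside the threshold of its updated neighbourhood, so extra passes
#' settle it. Because a cubic spline may overshoot and reproduce a value
#' the median-based detector keeps rejecting, beats still flagged after
#' two spline passes are snapped to the detector's own reference (the
#' local median of unflagged neighbours), which terminates the loop.
#' The union of all flags is reported.
#'
#' @inheritParams detect_artifacts
#' @return corrected [rr_series]; the cumulative artefact mask is
#'   attached as attribute `"artifact_mask"`.
#' @export
preprocess_rr <- function(series, threshold = 0.05) {
  out <- as_rr_series(series)
  total_mask <- logical(length(out$rr))
  for (pass in seq_len(10)) {
    mask <- detect_artifacts(out, threshold)
    if (!any(mask)) break
    if (pass <= 2) {
      out <- correct_artifacts(out, mask)
    } else {
      rr <- out$rr
      for (i in which(mask)) rr[i] <- local_median_ref(rr, mask, i)
      out <- rr_series(rr, out$sub_id, out$phase_id, out$test_id)
    }
    total_mask <- total_mask | mask
  }
  attr(out, "artifact_mask") <- total_mask
  out
}
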