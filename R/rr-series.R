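#' RR-interval series
#'
#' Container for a single short-term recording of RR (NN) intervals — the
#' times between consecutive normal heart beats — together with its position
#' in the measurement protocol: subject, phase (1 sitting, 2 lying,
#' 3 standing) and repetition.
#'
#' Beat times are the cumulative sums of the intervals, in seconds, so
#' `t[i] - t[i-1] == rr[i] / 1000` always holds.
#'
#' @param rr numeric vector of RR intervals in milliseconds; all positive
#'   and finite.
#' @param sub_id subject identifier.
#' @param phase_id protocol phase: 1 (sitting), 2 (lying) or 3 (standing).
#' @param test_id repetition number 1..4; 0 for the single sitting phase.
#' @return An object of class `rr_series`: a list with elements `rr` (ms),
#'   `t` (cumulative beat times, s), `sub_id`, `phase_id`, `test_id`.
#' @examples
#' s <- rr_series(rep(800, 150), sub_id = 1, phase_id = 2, test_id = 1)
#' length(s$rr)
#' @export
rr_series <- function(rr, sub_id = NA_integer_, phase_id = NA_integer_,
                      test_id = NA_integer_) {
  rr <- as.numeric(rr)
  if (length(rr) == 0) stop("empty RR series")
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("all RR intervals must be finite and positive")
  }
  if (!is.na(phase_id) && !phase_id %in% 1:3) {
    stop("phase_id must be 1 (sitting), 2 (lying) or 3 (standing)")
  }
  structure(
    list(rr = rr, t = cumsum(rr) / 1000,
         sub_id = sub_id, phase_id = phase_id, test_id = test_id),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "RR series: %d beats, %.1f s (subject %s, phase %s, repetition %s)\n",
    length(x$rr), sum(x$rr) / 1000,
    format(x$sub_id), format(x$phase_id), format(x$test_id)))
  cat(sprintf("  mean RR %.1f ms, SD %.1f ms\n",
              mean(x$rr), stats::sd(x$rr)))
  invisible(x)
}

# Coerce numeric input to an rr_series, passing rr_series through.
as_rr_series <- function(x) {
  if (inherits(x, "rr_series")) return(x)
  rr_series(x)
}
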