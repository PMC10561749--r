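# Validation utilities for comparing detected events against a reference
# (ground-truth) event list.

#' Match detected event times against reference times
#'
#' Greedy one-to-one nearest matching within a tolerance. Sensitivity is
#' the fraction of reference events matched; precision the fraction of
#' detected events that match a reference event.
#'
#' @param detected Numeric vector of detected event times, seconds.
#' @param reference Numeric vector of reference event times, seconds.
#' @param tol Matching tolerance, seconds.
#' @return List with `sensitivity`, `precision`, `errors` (detected minus
#'   reference for matched events, seconds) and `n_matched`.
#' @export
event_accuracy <- function(detected, reference, tol) {
  used <- logical(length(detected))
  err <- rep(NA_real_, length(reference))
  for (i in order(reference)) {
    d <- abs(detected - reference[i])
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      j <- which.min(d)
      used[j] <- TRUE
      err[i] <- detected[j] - reference[i]
    }
  }
  list(sensitivity = mean(!is.na(err)),
       precision = if (length(detected)) sum(used) / length(detected) else 0,
       errors = err[!is.na(err)],
       n_matched = sum(used))
}

#' Reference events interior to a window
#'
#' Reference event times restricted to the window shrunk by `margin` at
#' both ends; events at the very window boundary are not resolvable by any
#' detector (a peak needs neighbours on both sides).
#'
#' @param times Reference event times.
#' @param window An `analysis_window`.
#' @param margin Boundary margin in seconds (typically one stride time).
#' @return Filtered times.
#' @export
interior_events <- function(times, window, margin) {
  times[times >= window$t_start + margin & times <= window$t_end - margin]
}
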