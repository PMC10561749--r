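# Prominence-based peak picking. This primitive underlies both gait-event
# detectors, so it is implemented here rather than delegated: prominences are
# needed downstream as event scores for alternation tie-breaking.

#' Find local maxima with topographic prominence
#'
#' A sample is a candidate peak when it is strictly greater than its left
#' neighbour and at least its right neighbour (plateaus yield their first
#' sample). The prominence of a peak is its height above the higher of the
#' two lowest points separating it from higher terrain on either side.
#' Candidates are filtered by `min_prominence`, then thinned greedily in
#' decreasing height order so that surviving peaks are at least
#' `min_distance` samples apart.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence to keep a peak.
#' @param min_distance Minimum index spacing between kept peaks.
#' @return Data frame with columns `index`, `value`, `prominence`, sorted by
#'   index.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  empty <- data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  dx_l <- x[2:(n - 1)] - x[1:(n - 2)]
  dx_r <- x[3:n] - x[2:(n - 1)]
  cand <- which(dx_l > 0 & dx_r <= 0) + 1L
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left to nearest strictly higher sample, tracking the lowest col
    left <- if (i > 1) x[1:(i - 1)] else numeric(0)
    hi <- which(left > h)
    lo_l <- if (length(hi)) min(left[(max(hi) + 1):(i - 1)]) else min(left, h)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    hi <- which(right > h)
    lo_r <- if (length(hi)) min(right[1:(min(hi) - 1)]) else min(right, h)
    h - max(lo_l, lo_r)
  }, numeric(1))

  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  if (min_distance > 1 && length(cand) > 1) {
    ord <- order(x[cand], decreasing = TRUE)
    taken <- logical(length(cand))
    sel <- logical(length(cand))
    for (k in ord) {
      if (taken[k]) next
      sel[k] <- TRUE
      taken[abs(cand - cand[k]) < min_distance] <- TRUE
    }
    cand <- cand[sel]; prom <- prom[sel]
  }
  ord <- order(cand)
  data.frame(index = cand[ord], value = x[cand][ord],
             prominence = prom[ord])
}

# Quadratic (three-point) refinement of a peak location on a sampled signal;
# returns a fractional index. Used to place events with sub-sample timing.
refine_peak <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(as.numeric(i))
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom >= 0) return(as.numeric(i)) # not locally concave
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  as.numeric(i) + max(-0.5, min(0.5, delta))
}
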