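#' Normalize a ratio trace to [0, 1]
#'
#' Min-max normalization focusing the analysis on the appearance of nuclear
#' translocation maxima rather than absolute ratio levels. Constant traces
#' are mapped to all zeros and flagged degenerate.
#'
#' @param values numeric ratio values (non-finite entries dropped together
#'   with their times).
#' @param times matching times in minutes.
#' @return A `normalized_trace`: list with `times`, `values` in [0, 1] and
#'   `degenerate` flag.
#' @export
#' @examples
#' normalize_trace(c(2, 3, 4), c(0, 6, 12))$values
normalize_trace <- function(values, times = seq_along(values)) {
  keep <- is.finite(values) & is.finite(times)
  values <- values[keep]
  times <- times[keep]
  if (length(values) < 2)
    stop("normalize_trace: need >= 2 finite samples")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    out <- list(times = times, values = rep(0, length(values)),
                degenerate = TRUE)
  } else {
    out <- list(times = times, values = (values - rng[1]) / (rng[2] - rng[1]),
                degenerate = FALSE)
  }
  structure(out, class = "normalized_trace")
}

# Centered moving average; partial windows at the edges.
moving_average <- function(y, win) {
  win <- as.integer(win)
  if (win <= 1) return(y)
  half <- win %/% 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Topographic prominence of a strict local maximum at index i:
# drop from the peak to the higher of the two key saddles, where each saddle
# is the minimum between the peak and the nearest strictly higher point on
# that side (or the trace end if none is higher).
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- if (i == 1) h else {
    j <- i - 1
    while (j > 1 && y[j] <= h) j <- j - 1
    if (y[j] > h) min(y[(j + 1):(i - 1)]) else min(y[1:(i - 1)])
  }
  right <- if (i == length(y)) h else {
    j <- i + 1
    while (j < length(y) && y[j] <= h) j <- j + 1
    if (y[j] > h) min(y[(i + 1):(j - 1)]) else min(y[(i + 1):length(y)])
  }
  h - max(left, right)
}

#' Detect nuclear translocation peaks in a normalized trace
#'
#' The trace is smoothed with a centered moving average, strict local maxima
#' are found, their topographic prominence computed, maxima below
#' `min_prominence` discarded, and a minimum pairwise separation enforced by
#' keeping peaks in order of decreasing height (earliest first on ties).
#' Retained peak times are refined by quadratic interpolation through the
#' maximum and its two neighbours, giving sub-frame timing resolution.
#'
#' @param trace a `normalized_trace` from [normalize_trace()].
#' @param smooth_win moving-average window, frames (odd; 1 = no smoothing).
#' @param min_prominence minimum topographic prominence, normalized units.
#' @param min_separation_min minimum time between retained peaks, minutes.
#' @return data.frame with columns `time_min` (interpolated), `height`
#'   (smoothed value at the maximum), `index` (frame index of the discrete
#'   maximum) and `prominence`, ordered by time. Degenerate traces give zero
#'   rows.
#' @export
detect_peaks <- function(trace, smooth_win = 3, min_prominence = 0.1,
                         min_separation_min = 30) {
  stopifnot(inherits(trace, "normalized_trace"))
  empty <- data.frame(time_min = numeric(0), height = numeric(0),
                      index = integer(0), prominence = numeric(0))
  if (isTRUE(trace$degenerate)) return(empty)
  y <- moving_average(trace$values, smooth_win)
  t <- trace$times
  n <- length(y)
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  # separation: tallest first, earliest wins ties
  ord <- order(-y[cand], t[cand])
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(t[cand[i]] - t[cand[accepted]]) >= min_separation_min))
      accepted <- c(accepted, i)
  }
  cand <- cand[sort(accepted)]
  prom <- prom[sort(accepted)]
  ord2 <- order(t[cand])
  cand <- cand[ord2]
  prom <- prom[ord2]
  time_ref <- vapply(cand, function(i) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom >= 0) return(t[i])  # flat/degenerate curvature: no refinement
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    delta <- max(-0.5, min(0.5, delta))
    t[i] + delta * (t[i + 1] - t[i - 1]) / 2
  }, numeric(1))
  data.frame(time_min = time_ref, height = y[cand], index = cand,
             prominence = prom)
}
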