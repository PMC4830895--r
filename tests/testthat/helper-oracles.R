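# Independent oracles and tiny fixture builders used across the suite.

# Draw a filled disk into a matrix (independent of the package's renderer).
draw_disk <- function(img, row, col, radius, value) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - row)^2 + (c - col)^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

# Flood-fill connected-components count on a binary matrix, 8-connectivity.
flood_fill_components <- function(bw) {
  visited <- matrix(FALSE, nrow(bw), ncol(bw))
  n <- 0L
  for (r0 in seq_len(nrow(bw))) {
    for (c0 in seq_len(ncol(bw))) {
      if (!bw[r0, c0] || visited[r0, c0]) next
      n <- n + 1L
      queue <- list(c(r0, c0))
      visited[r0, c0] <- TRUE
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= nrow(bw) && c >= 1 && c <= ncol(bw) &&
              bw[r, c] && !visited[r, c]) {
            visited[r, c] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  n
}

# Exhaustive peak oracle: moving-average smoothing, full scan for strict
# local maxima, prominence by whole-trace scans, prominence filter, then
# iterative tallest-first (earliest on ties) separation enforcement.
oracle_peak_indices <- function(values, times, smooth_win = 3,
                                min_prominence = 0.1,
                                min_separation_min = 30) {
  n <- length(values)
  half <- as.integer(smooth_win) %/% 2
  y <- sapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    sum(values[idx]) / length(idx)
  })
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) cand <- c(cand, i)
  }
  prom <- sapply(cand, function(i) {
    h <- y[i]
    higher_left <- which(y[seq_len(i - 1)] > h)
    lb <- if (length(higher_left) == 0) min(y[seq_len(i - 1)])
          else min(y[(max(higher_left) + 1):(i - 1)])
    higher_right <- which(y[(i + 1):n] > h) + i
    rb <- if (length(higher_right) == 0) min(y[(i + 1):n])
          else min(y[(i + 1):(min(higher_right) - 1)])
    h - max(lb, rb)
  })
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(integer(0))
  remaining <- cand
  accepted <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[order(-y[remaining], times[remaining])][1]
    if (length(accepted) == 0 ||
        all(abs(times[best] - times[accepted]) >= min_separation_min))
      accepted <- c(accepted, best)
    remaining <- setdiff(remaining, best)
  }
  sort(accepted)
}

# Exact hypergeometric upper-tail sum: P(X >= k) when drawing s from a
# universe of size u containing m pathway genes.
oracle_hyper_tail <- function(k, m, u, s) {
  kk <- k:min(m, s)
  sum(choose(m, kk) * choose(u - m, s - kk)) / choose(u, s)
}

# Small deterministic toy DEG table: 6 genes x model treatments with known
# filter outcomes.
toy_deg_table <- function() {
  data.frame(
    gene = rep(c("G1", "G2", "G3", "G4", "G5", "G6"), each = 2),
    treatment = rep(c("model_oxidative", "model_inflammatory"), 6),
    treatment_class = rep(c("model_oxidative", "model_inflammatory"), 6),
    log2fc = c(1.6, 0.1,   # G1 passes oxidative
               3.0, 3.0,   # G2 p too large everywhere
               -2.1, 0.0,  # G3 passes on absolute value
               1.4, 1.4,   # G4 lfc below oxidative threshold
               1.9, 0.2,   # G5 expression too low
               1.5, 0.0),  # G6 boundary: all thresholds exactly met
    adj_p = c(0.04, 0.04, 0.06, 0.06, 0.01, 0.01, 0.04, 0.04, 0.04, 0.04,
              0.05, 0.05),
    avg_expr = c(6, 6, 9, 9, 8, 8, 8, 8, 4.5, 4.5, 5, 5),
    stringsAsFactors = FALSE)
}
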