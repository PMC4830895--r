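#' Track segmented nuclei across frames
#'
#' Greedy nearest-centroid frame-to-frame linking: candidate links between
#' active tracks and current-frame detections are taken in order of
#' increasing centroid distance; links farther than `max_disp_px` are never
#' made. An unmatched track ends (no gap closing); an unmatched detection
#' starts a new track. Tracks covering fewer than `min_coverage` of all
#' frames are discarded, excluding under-observed cells from downstream
#' oscillation statistics.
#'
#' @param labels_per_frame list of integer label matrices, one per frame.
#' @param max_disp_px gating radius in pixels.
#' @param min_coverage minimum fraction of the movie a track must span to be
#'   kept (default 0.8); set 0 to keep all.
#' @return data.frame with columns `track_id`, `frame` (1-based), `label`,
#'   `row`, `col`. Frames within a track are consecutive.
#' @export
track_nuclei <- function(labels_per_frame, max_disp_px = 10,
                         min_coverage = 0.8) {
  stopifnot(length(labels_per_frame) >= 1)
  cents <- lapply(labels_per_frame, label_centroids)
  rows <- list()
  next_id <- 1L
  active <- data.frame(track_id = integer(0), row = numeric(0),
                       col = numeric(0))
  for (f in seq_along(cents)) {
    det <- cents[[f]]
    assigned_det <- rep(FALSE, nrow(det))
    matched_track <- rep(FALSE, nrow(active))
    if (nrow(active) > 0 && nrow(det) > 0) {
      dmat <- outer(active$row, det$row, "-")^2 +
        outer(active$col, det$col, "-")^2
      cand <- which(dmat <= max_disp_px^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        for (ci in seq_len(nrow(cand))) {
          ti <- cand[ci, 1]; di <- cand[ci, 2]
          if (matched_track[ti] || assigned_det[di]) next
          matched_track[ti] <- TRUE
          assigned_det[di] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            track_id = active$track_id[ti], frame = f,
            label = det$label[di], row = det$row[di], col = det$col[di])
        }
      }
    }
    new_active <- data.frame(track_id = integer(0), row = numeric(0),
                             col = numeric(0))
    if (any(matched_track)) {
      m <- do.call(rbind, rows[(length(rows) - sum(matched_track) + 1L):
                                 length(rows)])
      new_active <- m[, c("track_id", "row", "col")]
    }
    for (di in which(!assigned_det)) {
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = next_id, frame = f, label = det$label[di],
        row = det$row[di], col = det$col[di])
      new_active <- rbind(new_active,
                          data.frame(track_id = next_id, row = det$row[di],
                                     col = det$col[di]))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  if (length(rows) == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      label = integer(0), row = numeric(0), col = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  if (min_coverage > 0) {
    len <- table(out$track_id)
    keep <- as.integer(names(len)[len >= min_coverage *
                                    length(labels_per_frame)])
    out <- out[out$track_id %in% keep, ]
    rownames(out) <- NULL
  }
  out
}
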