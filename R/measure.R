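#' Measure a nuclear/cytoplasmic ratio trace along a track
#'
#' For each frame of the track, the ratio is the mean reporter intensity over
#' the tracked nucleus mask divided by the mean over its cytoplasmic ring,
#' after subtracting the per-frame background estimate
#' ([frame_background()]) from both. Frames where the background-subtracted
#' cytoplasmic mean is not positive (or the ring is empty) are marked missing
#' (`NA`).
#'
#' @param track one track's rows from [track_nuclei()] (single `track_id`).
#' @param stack the [timelapse_stack()] holding the `reporter` channel.
#' @param nucleus_labels,cytoplasm_labels lists of per-frame label matrices.
#' @return data.frame with columns `frame`, `time_min`, `ratio`.
#' @export
measure_ratio <- function(track, stack, nucleus_labels, cytoplasm_labels) {
  stopifnot(inherits(stack, "timelapse_stack"),
            length(unique(track$track_id)) == 1)
  times <- stack_times(stack)
  ratio <- rep(NA_real_, nrow(track))
  for (i in seq_len(nrow(track))) {
    f <- track$frame[i]
    lab <- track$label[i]
    img <- get_frame(stack, "reporter", f)
    bg <- frame_background(img, nucleus_labels[[f]])
    nuc_px <- img[nucleus_labels[[f]] == lab]
    cyt_px <- img[cytoplasm_labels[[f]] == lab]
    if (length(nuc_px) == 0 || length(cyt_px) == 0) next
    cyt_mean <- mean(cyt_px) - bg
    if (cyt_mean <= 0) next
    ratio[i] <- (mean(nuc_px) - bg) / cyt_mean
  }
  data.frame(frame = track$frame, time_min = times[track$frame],
             ratio = ratio)
}

#' Full image-to-trace extraction
#'
#' Runs the whole measurement chain on a two-channel (nuclei + reporter)
#' stack: per-frame nucleus segmentation, greedy tracking, cytoplasmic ring
#' segmentation, and background-corrected ratio measurement per tracked cell.
#'
#' @param stack a [timelapse_stack()] with `nuclei` and `reporter` channels.
#' @param min_area_px,threshold,watershed_tolerance passed to
#'   [segment_nuclei()].
#' @param max_disp_px,min_coverage passed to [track_nuclei()].
#' @param ring_width_px passed to [segment_cytoplasm()].
#' @return A [ratio_traces()] collection on the stack's time base; frames a
#'   cell was not measured in are `NA`.
#' @export
extract_ratio_traces <- function(stack, min_area_px = 20, threshold = NULL,
                                 watershed_tolerance = 1, max_disp_px = 10,
                                 min_coverage = 0.8, ring_width_px = 4) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nf <- n_frames(stack)
  nuc_labels <- lapply(seq_len(nf), function(f)
    segment_nuclei(get_frame(stack, "nuclei", f), min_area_px = min_area_px,
                   threshold = threshold,
                   watershed_tolerance = watershed_tolerance))
  cyt_labels <- lapply(nuc_labels, segment_cytoplasm,
                       ring_width_px = ring_width_px)
  tracks <- track_nuclei(nuc_labels, max_disp_px = max_disp_px,
                         min_coverage = min_coverage)
  ids <- unique(tracks$track_id)
  values <- matrix(NA_real_, nrow = length(ids), ncol = nf)
  for (j in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[j], ]
    m <- measure_ratio(tr, stack, nuc_labels, cyt_labels)
    values[j, m$frame] <- m$ratio
  }
  ratio_traces(stack_times(stack), values, cell_ids = ids)
}
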