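#' Write a time-lapse stack as multi-page TIFF
#'
#' Pages are written frame-major with channels interleaved within each frame
#' (frame 1 channel 1, frame 1 channel 2, ..., frame 2 channel 1, ...), 16-bit
#' unsigned. Intensities are stored as `round(value)` counts; values outside
#' [0, 65535] are clipped.
#'
#' @param stack a [timelapse_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nf <- n_frames(stack)
  pages <- vector("list", nf * length(stack$channels))
  k <- 1L
  for (f in seq_len(nf)) {
    for (ch in names(stack$channels)) {
      m <- stack$channels[[ch]][, , f]
      m <- pmin(pmax(round(m), 0), 65535) / 65535
      pages[[k]] <- m
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @param channels character vector of channel role names, in the interleaving
#'   order used when writing.
#' @param frame_interval_min minutes between frames.
#' @param t0_min time of the first frame.
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(path, channels, frame_interval_min, t0_min = 0) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("read_stack_tiff: cannot read '", path,
                           "' as TIFF: ", conditionMessage(e)))
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("read_stack_tiff: page count ", length(pages),
         " is not a multiple of ", nc, " channels")
  nf <- length(pages) %/% nc
  d <- dim(pages[[1]])
  chans <- stats::setNames(
    lapply(seq_len(nc), function(ci) {
      arr <- array(0, dim = c(d[1], d[2], nf))
      for (f in seq_len(nf))
        arr[, , f] <- pages[[(f - 1L) * nc + ci]] * 65535
      arr
    }), channels)
  timelapse_stack(chans, frame_interval_min, t0_min)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a ground-truth list from a `simulate_*` generator.
#' @param path file path.
#' @return `write_truth_json` returns `path` invisibly; `read_truth_json`
#'   returns the truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
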