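#' Srxn1-GFP induction score of one frame
#'
#' The Nrf2 reporter score: connected components of pixels strictly above
#' background are found (8-connectivity), components smaller than
#' `min_blob_px` discarded (45 px is about one quarter of an average cell, so
#' sub-cellular speckles do not count), and the score is the total qualifying
#' pixel count multiplied by the average above-background density of those
#' pixels, normalized by the number of nuclei in the frame.
#'
#' @param reporter_image intensity matrix.
#' @param background scalar background intensity; pixels must exceed it
#'   strictly.
#' @param n_nuclei number of nuclei in the frame (>= 1).
#' @param min_blob_px minimum qualifying component size, pixels.
#' @param per_blob if `TRUE`, the density term is the mean of per-blob mean
#'   densities instead of the pooled mean over all qualifying pixels.
#' @param detect_threshold optional detection level for the blob mask, above
#'   which pixels count as positive (defaults to `background`); densities are
#'   always measured relative to `background`. Raising it above the
#'   background level keeps camera noise out of the mask on noisy images.
#' @return Scalar score (0 when no component qualifies).
#' @export
#' @examples
#' img <- matrix(0, 20, 20); img[5:14, 5:14] <- 3  # 100-px blob, density 3
#' srxn1_score(img, background = 0, n_nuclei = 10)  # 100 * 3 / 10 = 30
srxn1_score <- function(reporter_image, background, n_nuclei,
                        min_blob_px = 45, per_blob = FALSE,
                        detect_threshold = NULL) {
  if (n_nuclei < 1) stop("srxn1_score: n_nuclei must be >= 1")
  if (is.null(detect_threshold)) detect_threshold <- background
  bw <- reporter_image > max(background, detect_threshold)
  if (!any(bw)) return(0)
  labels <- EBImage::bwlabel(bw)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(reporter_image), ncol(reporter_image))
  sizes <- tabulate(labels[labels > 0])
  qual <- which(sizes >= min_blob_px)
  if (length(qual) == 0) return(0)
  px_mask <- labels %in% qual
  n_px <- sum(px_mask)
  dens <- reporter_image[px_mask] - background
  density <- if (per_blob) {
    mean(vapply(qual, function(l)
      mean(reporter_image[labels == l] - background), numeric(1)))
  } else {
    mean(dens)
  }
  n_px * density / n_nuclei
}

#' Reporter score time series
#'
#' Applies [srxn1_score()] to every frame of a stack, estimating background
#' and nuclei count per frame from the nuclei channel.
#'
#' @param stack a [timelapse_stack()] with `reporter` and `nuclei` channels.
#' @param min_blob_px,per_blob passed to [srxn1_score()].
#' @param nuclei_min_area_px minimum nucleus size for counting.
#' @return data.frame with columns `time_min`, `score`, `n_nuclei`,
#'   `background`.
#' @export
srxn1_score_series <- function(stack, min_blob_px = 45, per_blob = FALSE,
                               nuclei_min_area_px = 20) {
  stopifnot(inherits(stack, "timelapse_stack"))
  times <- stack_times(stack)
  out <- data.frame(time_min = times, score = NA_real_,
                    n_nuclei = NA_integer_, background = NA_real_)
  for (f in seq_len(n_frames(stack))) {
    nuc <- segment_nuclei(get_frame(stack, "nuclei", f),
                          min_area_px = nuclei_min_area_px)
    nn <- max(nuc)
    img <- get_frame(stack, "reporter", f)
    # reporter-positive area is sparse: the median is the background level;
    # blobs are detected 3 robust s.d. above it to keep camera noise out of
    # the mask, while densities stay relative to the background level
    bg <- stats::median(img)
    thr <- bg + 3 * stats::mad(img)
    out$n_nuclei[f] <- nn
    out$background[f] <- bg
    out$score[f] <- if (nn >= 1) srxn1_score(img, bg, nn,
                                             min_blob_px = min_blob_px,
                                             per_blob = per_blob,
                                             detect_threshold = thr)
                    else NA_real_
  }
  out
}

#' Fold induction of the Nrf2 reporter
#'
#' Treated-over-control ratio of the Srxn1-GFP score at the assay endpoint
#' (default 24 h = 1440 min).
#'
#' @param treated,control score series (data.frames with `time_min`, `score`)
#'   from [srxn1_score_series()].
#' @param at_min evaluation time; both series must cover it (nearest sampled
#'   time point is used).
#' @return Fold induction; `NA` with a warning if the control score is 0.
#' @export
fold_induction <- function(treated, control, at_min = 1440) {
  pick <- function(s) {
    if (at_min < min(s$time_min) || at_min > max(s$time_min))
      stop("fold_induction: series does not cover t = ", at_min, " min")
    s$score[which.min(abs(s$time_min - at_min))]
  }
  ct <- pick(control)
  if (!is.finite(ct) || ct == 0) {
    warning("fold_induction: control score is 0; fold undefined")
    return(NA_real_)
  }
  pick(treated) / ct
}

#' Annexin-V positive fraction of one frame
#'
#' Percentage of the occupied cell area that is Annexin-V positive: 100 times
#' the count of pixels strictly above background, divided by the total cell
#' area, capped at 100.
#'
#' @param death_image Annexin channel intensity matrix.
#' @param cell_area_px total cell-occupied area in pixels (> 0), e.g. from
#'   [cell_area_from_transmission()].
#' @param background scalar background intensity.
#' @return Percent in [0, 100].
#' @export
annexin_fraction <- function(death_image, cell_area_px, background) {
  if (cell_area_px <= 0) stop("annexin_fraction: cell_area_px must be > 0")
  pos <- sum(death_image > background)
  min(100, 100 * pos / cell_area_px)
}

#' Cell-occupied area from a transmission image
#'
#' Marks occupied pixels by local intensity variance (texture): cells show
#' intracellular texture while empty background is flat. The local variance
#' is computed in a square window and split into the flat and textured
#' classes by Otsu's threshold on the variance image (robust when the
#' background variance is essentially zero). The mask can extend up to half
#' a window beyond true cell boundaries.
#'
#' @param transmission_image intensity matrix.
#' @param window odd window side for the local variance, pixels.
#' @return Occupied area in pixels.
#' @export
cell_area_from_transmission <- function(transmission_image, window = 7) {
  img <- as.matrix(transmission_image)
  if (max(img) == min(img)) return(0L)
  brush <- matrix(1 / window^2, window, window)
  m1 <- EBImage::filter2(img, brush)
  m2 <- EBImage::filter2(img^2, brush)
  v <- pmax(m2 - m1^2, 0)
  vmax <- max(v)
  if (vmax == 0) return(0L)
  thr <- EBImage::otsu(EBImage::Image(v / vmax), range = c(0, 1))
  sum(v / vmax > thr)
}

#' Death-curve time series from an Annexin-V stack
#'
#' @param stack a [timelapse_stack()] with `death` and `transmission`
#'   channels.
#' @param background scalar Annexin background; default the first-frame
#'   median.
#' @param cell_area_px fixed occupied area; default estimated per frame from
#'   the transmission channel.
#' @return A `death_curve` data.frame with `time_min` and `percent_positive`.
#' @export
death_curve <- function(stack, background = NULL, cell_area_px = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  if (is.null(background))
    background <- stats::median(get_frame(stack, "death", 1))
  times <- stack_times(stack)
  pct <- vapply(seq_len(n_frames(stack)), function(f) {
    area <- if (is.null(cell_area_px))
      cell_area_from_transmission(get_frame(stack, "transmission", f))
    else cell_area_px
    if (area <= 0) return(NA_real_)
    annexin_fraction(get_frame(stack, "death", f), area, background)
  }, numeric(1))
  structure(data.frame(time_min = times, percent_positive = pct),
            class = c("death_curve", "data.frame"))
}

#' Area under a death curve
#'
#' Trapezoidal integral of percent-positive over time in hours, summarizing
#' the appearance of dead cells across the movie.
#'
#' @param curve data.frame with `time_min` and `percent_positive`.
#' @return AUC in percent x hours.
#' @export
#' @examples
#' death_auc(data.frame(time_min = c(0, 1440), percent_positive = c(0, 10)))
death_auc <- function(curve) {
  keep <- is.finite(curve$percent_positive)
  t_h <- curve$time_min[keep] / 60
  y <- curve$percent_positive[keep]
  if (length(y) < 2) return(NA_real_)
  sum(diff(t_h) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' TNFa cytotoxic synergy
#'
#' The apoptosis effect of TNFa co-exposure: percentage-point increase in
#' dead cells when TNFa is added after drug pre-exposure, relative to drug
#' alone.
#'
#' @param pct_drug percent dead cells with drug alone, in [0, 100].
#' @param pct_drug_tnf percent dead cells with drug plus TNFa, in [0, 100].
#' @return `pct_drug_tnf - pct_drug`, percentage points.
#' @export
#' @examples
#' tnf_synergy(3.9, 22.5)  # carbamazepine: 18.6
tnf_synergy <- function(pct_drug, pct_drug_tnf) {
  if (any(pct_drug < 0 | pct_drug > 100) ||
      any(pct_drug_tnf < 0 | pct_drug_tnf > 100))
    stop("tnf_synergy: percentages must lie in [0, 100]")
  pct_drug_tnf - pct_drug
}
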