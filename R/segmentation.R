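#' Segment nuclei in a Hoechst image
#'
#' Global-threshold segmentation with distance-transform watershed splitting
#' of touching nuclei. The threshold defaults to Otsu's method on the image
#' histogram; a fixed threshold can be supplied for full reproducibility on
#' synthetic fixtures. Components smaller than `min_area_px` are removed and
#' labels renumbered consecutively.
#'
#' @param img single-channel numeric matrix.
#' @param min_area_px minimum component area kept, pixels.
#' @param threshold optional fixed intensity threshold; pixels strictly above
#'   it are foreground. `NULL` uses Otsu.
#' @param watershed_tolerance minimum object height separating two watershed
#'   objects (passed to [EBImage::watershed()]).
#' @return Integer label matrix (0 = background). A blank or constant image
#'   yields zero labels, not an error.
#' @export
segment_nuclei <- function(img, min_area_px = 20, threshold = NULL,
                           watershed_tolerance = 1) {
  img <- as.matrix(img)
  rng <- range(img, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    return(matrix(0L, nrow(img), ncol(img)))
  if (is.null(threshold)) {
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(norm) * (rng[2] - rng[1])
  }
  bw <- img > threshold
  if (!any(bw)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(bw)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  labels <- EBImage::imageData(labels)
  drop_small_relabel(labels, min_area_px)
}

# Remove components below min_area and renumber labels 1..n.
drop_small_relabel <- function(labels, min_area_px) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area_px)
  map <- integer(length(tab))
  map[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- map[labels[pos]]
  labels
}

#' Centroids and areas of a label image
#'
#' @param labels integer label matrix.
#' @return data.frame with columns `label`, `row`, `col` (centroid, 1-based
#'   pixel coordinates) and `area` (pixels).
#' @export
label_centroids <- function(labels) {
  pos <- which(labels > 0, arr.ind = TRUE)
  if (nrow(pos) == 0)
    return(data.frame(label = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0)))
  lab <- labels[pos]
  data.frame(
    label = sort(unique(lab)),
    row = as.numeric(tapply(pos[, 1], lab, mean)),
    col = as.numeric(tapply(pos[, 2], lab, mean)),
    area = as.integer(tapply(lab, lab, length)),
    row.names = NULL)
}

#' Segment cytoplasmic rings around segmented nuclei
#'
#' The cytoplasmic region of each cell is a ring of width `ring_width_px`
#' obtained by disc dilation of the nuclear masks, minus all nuclei. Where
#' rings of neighbouring cells would overlap, pixels are assigned to the
#' nearest nucleus (Voronoi-style label propagation), so rings form a
#' partition and are pairwise disjoint.
#'
#' @param nucleus_labels integer label matrix from [segment_nuclei()].
#' @param ring_width_px ring width in pixels; 0 yields an empty cytoplasm
#'   image (downstream ratios are then flagged missing).
#' @return Integer label matrix of cytoplasm regions sharing nucleus labels.
#' @export
segment_cytoplasm <- function(nucleus_labels, ring_width_px) {
  nucleus_labels <- matrix(as.integer(nucleus_labels),
                           nrow(nucleus_labels), ncol(nucleus_labels))
  out <- matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels))
  if (ring_width_px <= 0 || !any(nucleus_labels > 0)) return(out)
  brush <- EBImage::makeBrush(2L * as.integer(ring_width_px) + 1L, "disc")
  mask <- EBImage::dilate(nucleus_labels > 0, brush)
  prop <- EBImage::propagate(x = matrix(0, nrow(nucleus_labels),
                                        ncol(nucleus_labels)),
                             seeds = nucleus_labels, mask = mask)
  prop <- matrix(as.integer(EBImage::imageData(prop)),
                 nrow(nucleus_labels), ncol(nucleus_labels))
  prop[nucleus_labels > 0] <- 0L
  prop
}

#' Per-frame background estimate
#'
#' Median intensity of pixels outside all dilated nuclei; if the nuclei cover
#' the whole frame, falls back to the overall median.
#'
#' @param img intensity matrix.
#' @param nucleus_labels label matrix of the same frame.
#' @param dilate_px safety margin dilation applied to nuclei before exclusion.
#' @return Scalar background intensity.
#' @export
frame_background <- function(img, nucleus_labels, dilate_px = 5) {
  fg <- nucleus_labels > 0
  if (any(fg) && dilate_px > 0)
    fg <- EBImage::dilate(fg, EBImage::makeBrush(2L * dilate_px + 1L, "disc"))
  bgpx <- img[!fg]
  if (length(bgpx) == 0) bgpx <- img
  stats::median(bgpx)
}
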