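#' Plot the mean normalized translocation trace with peak markers
#'
#' @param summary result of [population_summary()].
#' @param peaks optional peak table from [detect_peaks()] on the mean trace;
#'   if `NULL`, peaks are detected with default parameters.
#' @param file optional output path (`.png` or `.svg`); `NULL` draws on the
#'   current device.
#' @param main plot title.
#' @return The peak table used, invisibly.
#' @export
plot_mean_trace <- function(summary, peaks = NULL, file = NULL,
                            main = "Mean normalized GFP-p65 N/C ratio") {
  mt <- summary$mean_normalized_trace
  if (is.null(peaks))
    peaks <- detect_peaks(normalize_trace(mt$value, mt$time_min))
  if (!is.null(file)) open_device(file, width = 7, height = 4)
  graphics::plot(mt$time_min, mt$value, type = "l", lwd = 2,
                 xlab = "Time after TNFa (min)",
                 ylab = "Normalized N/C ratio", main = main)
  if (nrow(peaks) > 0)
    graphics::points(peaks$time_min,
                     stats::approx(mt$time_min, mt$value,
                                   xout = peaks$time_min)$y + 0.04,
                     pch = 25, bg = "red", col = "red")
  if (!is.null(file)) grDevices::dev.off()
  invisible(peaks)
}

#' Bar-and-arrow enrichment plot
#'
#' Bars show -log10 right-tail Fisher p per pathway; arrows above each bar
#' encode the mean fold change of the genes driving the significance (length
#' = magnitude, direction = mean up- or downregulation).
#'
#' @param enrichment data.frame from [enrich_all()].
#' @param file optional output path; `NULL` draws on the current device.
#' @param main title.
#' @return `enrichment`, invisibly.
#' @export
plot_enrichment <- function(enrichment, file = NULL,
                            main = "Pathway enrichment") {
  if (!is.null(file)) open_device(file, width = 7, height = 4.5)
  mids <- graphics::barplot(enrichment$minus_log10_p,
                            names.arg = enrichment$pathway, las = 2,
                            ylab = expression(-log[10] ~ italic(p)),
                            main = main,
                            ylim = c(0, max(enrichment$minus_log10_p) * 1.4),
                            cex.names = 0.7)
  scale <- 0.15 * max(enrichment$minus_log10_p) /
    max(enrichment$magnitude, 1, na.rm = TRUE)
  for (i in seq_len(nrow(enrichment))) {
    if (!is.finite(enrichment$magnitude[i]) ||
        enrichment$direction[i] == 0) next
    y0 <- enrichment$minus_log10_p[i] + 0.05 * max(enrichment$minus_log10_p)
    graphics::arrows(mids[i], y0, mids[i],
                     y0 + enrichment$direction[i] *
                       enrichment$magnitude[i] * scale,
                     length = 0.06, lwd = 2, col = "steelblue")
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(enrichment)
}

#' Clustered fold-change heatmap
#'
#' Uses pheatmap when available (drawing the stored Ward/Manhattan trees);
#' otherwise falls back to a base-graphics image of the clustered matrix.
#'
#' @param result a `cluster_result` from [cluster_heatmap()].
#' @param file optional output path; `NULL` draws on the current device.
#' @return `result`, invisibly.
#' @export
plot_cluster_heatmap <- function(result, file = NULL) {
  if (!is.null(file)) open_device(file, width = 6, height = 7)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(result$matrix, cluster_rows = FALSE,
                       cluster_cols = FALSE,
                       color = grDevices::colorRampPalette(
                         c("blue", "black", "orange"))(64))
  } else {
    graphics::image(t(result$matrix)[, rev(seq_len(nrow(result$matrix)))],
                    axes = FALSE, main = "log2 fold change (clustered)")
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(result)
}

open_device <- function(file, width, height) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(file, width = width, height = height),
    stop("unsupported figure format: .", ext))
}
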