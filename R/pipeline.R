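#' Pipeline run configuration
#'
#' One configuration object drives both simulation and analysis runs of a
#' single assay. Assays: `p65` (NF-kB translocation oscillations), `srxn1`
#' (Nrf2 reporter induction), `annexin` (cell-death curves) and `genesets`
#' (transcriptomics clustering/enrichment).
#'
#' @param assay one of `"p65"`, `"srxn1"`, `"annexin"`, `"genesets"`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in all outputs.
#' @param sim list of [sim_config()] overrides for `simulate` runs.
#' @param analysis list of analysis parameter overrides (peak detection,
#'   segmentation gates, filter thresholds, ...).
#' @param inputs named list of input paths for `analyze` runs (e.g. `stack`,
#'   `deg_table`, `gmt`).
#' @return A `run_config` list.
#' @export
run_config <- function(assay, out_dir, seed = 1L, sim = list(),
                       analysis = list(), inputs = list()) {
  assay <- match.arg(assay, c("p65", "srxn1", "annexin", "genesets"))
  structure(list(assay = assay, out_dir = out_dir, seed = as.integer(seed),
                 sim = sim, analysis = analysis, inputs = inputs),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# Default assay timings: p65 6 min x 6 h; srxn1/annexin 30 min x 24 h.
assay_sim_config <- function(config) {
  defaults <- switch(config$assay,
    p65 = list(frame_interval_min = 6, duration_min = 360),
    srxn1 = list(frame_interval_min = 30, duration_min = 1440),
    annexin = list(frame_interval_min = 30, duration_min = 1440),
    genesets = list())
  args <- utils::modifyList(defaults, config$sim)
  args$seed <- config$seed
  do.call(sim_config, args)
}

write_manifest <- function(config, files, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    assay = config$assay, seed = config$seed,
    package_version = as.character(utils::packageVersion("hepadyn")),
    config = unclass(config),
    artifacts = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate an assay's input data to disk
#'
#' Writes the synthetic inputs for the configured assay (image stacks as
#' 16-bit multi-page TIFF, DEG tables as TSV), exact ground truth as JSON,
#' the effective configuration as YAML, and a manifest JSON with MD5 hashes
#' of every artifact. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  cfg <- assay_sim_config(config)
  write_sim_config(cfg, out("sim_config.yaml"))
  files <- c(config = out("sim_config.yaml"))
  if (config$assay == "p65") {
    sim <- simulate_ratio_traces(cfg)
    stack <- render_p65_stack(sim$traces, cfg)
    write_stack_tiff(stack, out("p65_stack.tif"))
    write_truth_json(sim$truth, out("truth.json"))
    utils::write.table(
      data.frame(cell_id = rep(sim$traces$cell_ids,
                               each = length(sim$traces$times)),
                 time_min = rep(sim$traces$times,
                                times = nrow(sim$traces$values)),
                 ratio = as.vector(t(sim$traces$values))),
      out("true_traces.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, stack = out("p65_stack.tif"),
               truth = out("truth.json"), traces = out("true_traces.tsv"))
    message("run_simulate[p65]: ", cfg$n_cells, " cells, ",
            length(sim$traces$times), " frames")
  } else if (config$assay == "srxn1") {
    sim <- simulate_srxn1_stack(cfg)
    write_stack_tiff(sim$stack, out("srxn1_stack.tif"))
    write_truth_json(sim$truth["onset_min"], out("truth.json"))
    files <- c(files, stack = out("srxn1_stack.tif"),
               truth = out("truth.json"))
  } else if (config$assay == "annexin") {
    with_tnf <- isTRUE(config$sim$with_tnf)
    sim <- simulate_death_series(cfg, with_tnf = with_tnf)
    write_stack_tiff(sim$stack, out("annexin_stack.tif"))
    write_truth_json(sim$truth[c("death_time_min", "cell_area_px")],
                     out("truth.json"))
    files <- c(files, stack = out("annexin_stack.tif"),
               truth = out("truth.json"))
  } else {
    deg <- simulate_deg_table(cfg)
    write_deg_table(deg$table, out("deg_table.tsv"))
    write_truth_json(list(blocks = as.list(deg$blocks)), out("truth.json"))
    files <- c(files, deg_table = out("deg_table.tsv"),
               truth = out("truth.json"))
  }
  write_manifest(config, files, out("manifest.json"))
  files <- c(files, manifest = out("manifest.json"))
  invisible(files)
}

#' Analyze an assay's inputs and write result tables and figures
#'
#' Dispatches on `config$assay`:
#' \itemize{
#'   \item `p65`: image-to-trace extraction, per-cell oscillation features
#'     (JSON), population summary (TSV), mean-trace figure (PNG).
#'   \item `srxn1`: reporter score time series (TSV).
#'   \item `annexin`: death curve (TSV) with AUC in a summary JSON.
#'   \item `genesets`: responsiveness filtering, Manhattan/Ward clustering
#'     (clustered matrix TSV + dendrogram orders JSON) and Fisher enrichment
#'     (TSV) with a heatmap and bar/arrow figure (PNG).
#' }
#' Input paths default to the artifacts [run_simulate()] writes into
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  inp <- function(name, default) {
    p <- if (!is.null(config$inputs[[name]])) config$inputs[[name]]
         else out(default)
    if (!file.exists(p)) stop("run_analyze: missing input '", p, "'")
    p
  }
  cfg <- assay_sim_config(config)
  an <- config$analysis
  files <- character(0)
  if (config$assay == "p65") {
    stack_path <- inp("stack", "p65_stack.tif")
    stack <- read_stack_tiff(stack_path,
                             channels = c("nuclei", "reporter"),
                             frame_interval_min = cfg$frame_interval_min)
    traces <- extract_ratio_traces(
      stack,
      max_disp_px = an$max_disp_px %||% 10,
      min_coverage = an$min_coverage %||% 0.8,
      ring_width_px = an$ring_width_px %||% cfg$ring_width_px)
    message("run_analyze[p65]: ", nrow(traces$values), " tracked cells")
    feats <- analyze_traces(traces)
    summ <- population_summary(traces)
    jsonlite::write_json(lapply(feats, unclass), out("features.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    hist_df <- data.frame(peak_class = names(summ$histogram$counts),
                          n_cells = as.integer(summ$histogram$counts))
    utils::write.table(hist_df, out("peak_histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_cells = summ$n_cells,
           fraction_ge3 = summ$histogram$fraction_ge3,
           mean_delay_p1_p2_min = summ$mean_delay_p1_p2_min,
           mean_second_peak_min = summ$mean_second_peak_min),
      out("population_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    plot_mean_trace(summ, file = out("mean_trace.png"))
    files <- c(features = out("features.json"),
               histogram = out("peak_histogram.tsv"),
               summary = out("population_summary.json"),
               figure = out("mean_trace.png"))
  } else if (config$assay == "srxn1") {
    stack_path <- inp("stack", "srxn1_stack.tif")
    stack <- read_stack_tiff(stack_path,
                             channels = c("reporter", "nuclei"),
                             frame_interval_min = cfg$frame_interval_min)
    series <- srxn1_score_series(stack,
                                 min_blob_px = an$min_blob_px %||% 45)
    utils::write.table(series, out("srxn1_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(scores = out("srxn1_scores.tsv"))
  } else if (config$assay == "annexin") {
    stack_path <- inp("stack", "annexin_stack.tif")
    stack <- read_stack_tiff(stack_path,
                             channels = c("death", "transmission", "nuclei"),
                             frame_interval_min = cfg$frame_interval_min)
    curve <- death_curve(stack)
    utils::write.table(curve, out("death_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc_pct_h = death_auc(curve),
           end_pct = curve$percent_positive[nrow(curve)]),
      out("death_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files <- c(curve = out("death_curve.tsv"),
               summary = out("death_summary.json"))
  } else {
    deg_path <- inp("deg_table", "deg_table.tsv")
    table <- read_deg_table(deg_path)
    if (nrow(table) == 0) {
      warning("run_analyze[genesets]: empty DEG table; writing empty outputs")
      utils::write.table(table, out("filtered_genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      return(invisible(c(filtered = out("filtered_genes.tsv"))))
    }
    catalogs <- if (!is.null(config$inputs$gmt)) {
      lapply(config$inputs$gmt, read_gmt)
    } else NULL
    candidates <- if (!is.null(catalogs))
      union_catalog(catalogs)$gene else unique(table$gene)
    spec <- do.call(filter_spec, an$filter %||% list())
    kept <- suppressWarnings(
      filter_responsive(table, candidates, spec,
                        category = an$category %||%
                          names(spec$abs_lfc_min)[1]))
    message("run_analyze[genesets]: ", length(kept), " of ",
            length(candidates), " candidate genes pass the filter")
    writeLines(kept, out("filtered_genes.txt"))
    files <- c(filtered = out("filtered_genes.txt"))
    if (length(kept) >= 2) {
      cl <- cluster_heatmap(table, kept, k = an$k %||% 2)
      utils::write.table(
        data.frame(gene = rownames(cl$matrix), cl$matrix,
                   check.names = FALSE),
        out("clustered_matrix.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(gene_order = cl$gene_order,
             treatment_order = cl$treatment_order,
             gene_clusters = as.list(cl$gene_clusters)),
        out("dendrogram_orders.json"), auto_unbox = TRUE, pretty = TRUE)
      plot_cluster_heatmap(cl, file = out("heatmap.png"))
      files <- c(files, matrix = out("clustered_matrix.tsv"),
                 orders = out("dendrogram_orders.json"),
                 heatmap = out("heatmap.png"))
    }
    if (!is.null(catalogs)) {
      enr <- enrich_all(table, do.call(c, lapply(catalogs, unclass)),
                        treatment = an$treatment %||% "dili_severe")
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      plot_enrichment(enr, file = out("enrichment.png"))
      files <- c(files, enrichment = out("enrichment.tsv"),
                 enrichment_figure = out("enrichment.png"))
    }
  }
  write_manifest(config, files, out("analysis_manifest.json"))
  files <- c(files, manifest = out("analysis_manifest.json"))
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine per-condition results into a summary table
#'
#' Builds one row per condition in the style of a per-drug assay summary:
#' Srxn1-GFP fold induction, NF-kB second-peak delay versus control, percent
#' dead cells with and without TNFa, and the TNFa synergy in percentage
#' points. Each condition is described by a named list of available
#' quantities; missing quantities are reported as `NA`, never fabricated.
#'
#' @param conditions named list; each element a list with any of
#'   `fold_induction`, `delay_min`, `pct_dead`, `pct_dead_tnf`.
#' @param path optional TSV output path.
#' @return data.frame with one row per condition, columns `condition`,
#'   `fold_induction`, `delay_min`, `pct_dead`, `pct_dead_tnf`,
#'   `synergy_pct`.
#' @export
run_report <- function(conditions, path = NULL) {
  stopifnot(is.list(conditions), !is.null(names(conditions)))
  num <- function(x) if (is.null(x) || !is.finite(suppressWarnings(
    as.numeric(x)))) NA_real_ else as.numeric(x)
  rows <- lapply(names(conditions), function(nm) {
    cn <- conditions[[nm]]
    pd <- num(cn$pct_dead)
    pdt <- num(cn$pct_dead_tnf)
    data.frame(condition = nm,
               fold_induction = num(cn$fold_induction),
               delay_min = num(cn$delay_min),
               pct_dead = pd, pct_dead_tnf = pdt,
               synergy_pct = if (is.finite(pd) && is.finite(pdt))
                 tnf_synergy(pd, pdt) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
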