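#' Read / write gene sets in GMT format
#'
#' `read_gmt()` returns a gene-set catalog: a named list of gene vectors with
#' a `source` attribute tagging where the catalog came from (pathway
#' database, ontology, transcription-factor motif database, ...).
#'
#' @param path GMT file path.
#' @param source source tag attached to every set in the file.
#' @return A `gene_set_catalog`: named list of character vectors with a
#'   `source` attribute.
#' @export
read_gmt <- function(path, source = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  structure(sets, source = source, class = "gene_set_catalog")
}

#' @rdname read_gmt
#' @param catalog named list of gene vectors.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog), function(nm) {
    paste(c(nm, "na", catalog[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set catalog in code
#'
#' @param sets named list of gene vectors.
#' @param source source tag.
#' @return A `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, source = "custom") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(vapply(sets, function(g) any(!nzchar(g)), logical(1))))
    stop("gene_set_catalog: genes must be non-empty strings")
  structure(lapply(sets, unique), source = source,
            class = "gene_set_catalog")
}

#' Deduplicated union of gene-set catalogs
#'
#' Pools all genes appearing in any set of any catalog for one signaling
#' category (e.g. oxidative stress or inflammatory signaling), preserving
#' per-gene provenance: which source catalogs contributed each gene.
#'
#' @param catalogs list of `gene_set_catalog` objects.
#' @param category label attached to the result.
#' @return data.frame with columns `gene`, `sources` (comma-separated source
#'   tags) and `category`; one row per unique gene.
#' @export
union_catalog <- function(catalogs, category = "geneset") {
  if (inherits(catalogs, "gene_set_catalog")) catalogs <- list(catalogs)
  src_of <- list()
  for (cat in catalogs) {
    src <- attr(cat, "source")
    if (is.null(src)) src <- "unknown"
    for (genes in cat) {
      for (g in unique(genes)) {
        src_of[[g]] <- union(src_of[[g]], src)
      }
    }
  }
  genes <- sort(names(src_of))
  data.frame(gene = genes,
             sources = vapply(src_of[genes], paste, "", collapse = ","),
             category = category, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Responsiveness filter specification
#'
#' Thresholds of the model-compound responsiveness filter: a gene is kept
#' when, for at least one model treatment, its multiple-testing-corrected p
#' value is at most `adj_p_max`, its average log2 expression at least
#' `avg_expr_min`, and its absolute log2 fold change at least the
#' category-specific `abs_lfc_min`. All comparisons are inclusive. Defaults
#' are p 0.05, expression 5 (log2) and |log2FC| 1.5 for the oxidative stress
#' set versus 2.0 for the inflammatory set (different fold-change cutoffs
#' keep the two filtered sets comparable in size).
#'
#' @param adj_p_max maximum adjusted p.
#' @param avg_expr_min minimum average log2 expression.
#' @param abs_lfc_min named vector of minimum |log2FC| per category.
#' @param model_subset treatment labels used for filtering.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(adj_p_max = 0.05, avg_expr_min = 5,
                        abs_lfc_min = c(oxidative = 1.5, inflammatory = 2.0),
                        model_subset = c("model_oxidative",
                                         "model_inflammatory")) {
  stopifnot(adj_p_max > 0, avg_expr_min > 0, all(abs_lfc_min > 0))
  structure(list(adj_p_max = adj_p_max, avg_expr_min = avg_expr_min,
                 abs_lfc_min = abs_lfc_min, model_subset = model_subset),
            class = "filter_spec")
}

#' Filter a gene list for responsiveness in model treatments
#'
#' @param table DEG table (see [read_deg_table()]).
#' @param genes candidate gene list (e.g. from [union_catalog()]).
#' @param spec a [filter_spec()].
#' @param category which `abs_lfc_min` entry applies.
#' @return Character vector of surviving genes. Candidate genes absent from
#'   the table are dropped with a warning.
#' @export
filter_responsive <- function(table, genes, spec = filter_spec(),
                              category = names(spec$abs_lfc_min)[1]) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!category %in% names(spec$abs_lfc_min))
    stop("filter_responsive: unknown category '", category, "'")
  missing_tr <- setdiff(spec$model_subset, unique(table$treatment))
  if (length(missing_tr))
    stop("filter_responsive: model treatments absent from table: ",
         paste(missing_tr, collapse = ", "))
  absent <- setdiff(genes, unique(table$gene))
  if (length(absent))
    warning("filter_responsive: ", length(absent),
            " candidate gene(s) absent from the table; dropped")
  genes <- intersect(genes, unique(table$gene))
  lfc_min <- spec$abs_lfc_min[[category]]
  sub <- table[table$treatment %in% spec$model_subset &
                 table$gene %in% genes, ]
  hit <- sub$adj_p <= spec$adj_p_max &
    sub$avg_expr >= spec$avg_expr_min &
    abs(sub$log2fc) >= lfc_min
  intersect(genes, unique(sub$gene[hit]))
}

#' Select differentially expressed genes for one treatment
#'
#' Selection used upstream of pathway enrichment: genes with absolute log2
#' fold change of at least `lfc_min`, adjusted p of at most `p_max` and
#' average log2 expression of at least `expr_min` for the given treatment.
#' All bounds inclusive.
#'
#' @param table DEG table.
#' @param treatment treatment label.
#' @param lfc_min,p_max,expr_min thresholds (defaults 1.3, 0.05, 7).
#' @return Character vector of selected genes.
#' @export
select_deg <- function(table, treatment, lfc_min = 1.3, p_max = 0.05,
                       expr_min = 7) {
  sub <- table[table$treatment == treatment, ]
  sel <- abs(sub$log2fc) >= lfc_min & sub$adj_p <= p_max &
    sub$avg_expr >= expr_min
  unique(sub$gene[sel])
}
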