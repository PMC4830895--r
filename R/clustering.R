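#' Two-way Manhattan/Ward clustering of a fold-change matrix
#'
#' Builds the gene x treatment log2 fold-change matrix for the given genes
#' and treatments, computes pairwise Manhattan distances between genes and
#' between treatments, and applies Ward linkage to both. The default linkage
#' is `"ward.D"`, which reproduces the legacy "ward" method as applied
#' directly to a Manhattan distance matrix; `"ward.D2"` and Euclidean
#' distances are available for the textbook Ward criterion. Missing
#' (gene, treatment) fold changes are imputed as 0 with a warning (imputation
#' is for clustering only, never for filtering).
#'
#' @param table DEG table.
#' @param genes genes to cluster (rows).
#' @param treatments treatment labels to cluster (columns); default all in
#'   the table.
#' @param k number of flat gene clusters cut from the gene tree.
#' @param k_treatments optional flat cut of the treatment tree.
#' @param distance `"manhattan"` (default) or `"euclidean"`.
#' @param linkage `"ward.D"` (default) or `"ward.D2"`.
#' @return A `cluster_result` list: `matrix` (the fold-change matrix in
#'   clustered order), `gene_order`, `treatment_order`, `gene_tree`,
#'   `treatment_tree` (hclust objects), `gene_clusters` (named vector of flat
#'   labels at cut `k`), `treatment_clusters` (or `NULL`).
#' @export
cluster_heatmap <- function(table, genes, treatments = NULL, k = 2,
                            k_treatments = NULL,
                            distance = c("manhattan", "euclidean"),
                            linkage = c("ward.D", "ward.D2")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.null(treatments)) treatments <- unique(table$treatment)
  genes <- unique(genes)
  if (length(genes) < 2 || length(treatments) < 2)
    stop("cluster_heatmap: need >= 2 genes and >= 2 treatments")
  m <- matrix(NA_real_, length(genes), length(treatments),
              dimnames = list(genes, treatments))
  sub <- table[table$gene %in% genes & table$treatment %in% treatments, ]
  m[cbind(match(sub$gene, genes), match(sub$treatment, treatments))] <-
    sub$log2fc
  if (anyNA(m)) {
    warning("cluster_heatmap: ", sum(is.na(m)),
            " missing fold change(s) imputed as 0")
    m[is.na(m)] <- 0
  }
  gene_tree <- stats::hclust(stats::dist(m, method = distance),
                             method = linkage)
  treat_tree <- stats::hclust(stats::dist(t(m), method = distance),
                              method = linkage)
  gene_clusters <- stats::cutree(gene_tree, k = k)
  treat_clusters <- if (!is.null(k_treatments))
    stats::cutree(treat_tree, k = k_treatments) else NULL
  structure(list(
    matrix = m[gene_tree$order, treat_tree$order, drop = FALSE],
    gene_order = genes[gene_tree$order],
    treatment_order = treatments[treat_tree$order],
    gene_tree = gene_tree, treatment_tree = treat_tree,
    gene_clusters = gene_clusters, treatment_clusters = treat_clusters
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "treatments;", length(unique(x$gene_clusters)), "gene clusters\n")
  invisible(x)
}

#' Sweep the fold-change threshold of the responsiveness filter
#'
#' Utility for choosing category-specific |log2FC| cutoffs that yield
#' comparable filtered gene-set sizes across categories.
#'
#' @param table DEG table.
#' @param genes candidate genes.
#' @param spec a [filter_spec()].
#' @param category filter category.
#' @param lfc_grid fold-change thresholds to evaluate.
#' @return data.frame with `abs_lfc_min` and `n_genes` surviving.
#' @export
sweep_lfc_threshold <- function(table, genes, spec = filter_spec(),
                                category = names(spec$abs_lfc_min)[1],
                                lfc_grid = seq(0.5, 3, by = 0.25)) {
  n <- vapply(lfc_grid, function(th) {
    sp <- spec
    sp$abs_lfc_min[[category]] <- th
    length(suppressWarnings(
      filter_responsive(table, genes, sp, category = category)))
  }, integer(1))
  data.frame(abs_lfc_min = lfc_grid, n_genes = n)
}
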