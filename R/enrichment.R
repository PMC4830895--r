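#' Right-tailed Fisher exact pathway enrichment
#'
#' Over-representation of a pathway among selected (differentially
#' expressed) genes: the right tail of the hypergeometric distribution,
#' \eqn{p = P(X \ge k)} for observing overlap \eqn{k} when drawing
#' \eqn{|selected|} genes from a universe containing \eqn{|pathway|}
#' pathway genes. The pathway is first intersected with the universe; the
#' selected list must be a subset of the universe.
#'
#' @param selected selected gene list (subset of `universe`).
#' @param pathway pathway gene list.
#' @param universe background gene list (non-empty).
#' @return List with `overlap_genes`, `overlap` (count), `p` (right-tail
#'   Fisher exact), `minus_log10_p`, `pathway_size` (effective, within the
#'   universe), `selected_size`, `universe_size`.
#' @export
#' @examples
#' fisher_enrichment(letters[1:5], letters[3:10], letters)$p
fisher_enrichment <- function(selected, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("fisher_enrichment: empty universe")
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop("fisher_enrichment: selected genes must be a subset of the universe")
  pathway <- intersect(unique(pathway), universe)
  overlap <- intersect(selected, pathway)
  k <- length(overlap)
  m <- length(pathway)
  n <- length(universe) - m
  s <- length(selected)
  p <- stats::phyper(k - 1, m, n, s, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(overlap_genes = overlap, overlap = k, p = p,
       minus_log10_p = -log10(p), pathway_size = m, selected_size = s,
       universe_size = length(universe))
}

#' Mean fold-change vector of the genes driving an enrichment
#'
#' Summarizes the genes responsible for a pathway's significance as an
#' arrow: magnitude = mean absolute log2 fold change over the overlap genes,
#' direction = sign of the mean signed log2 fold change (+1 mean
#' upregulation, -1 mean downregulation, 0 balanced).
#'
#' @param overlap overlap gene list.
#' @param table DEG table.
#' @param treatment treatment label.
#' @return List with `magnitude`, `direction` (-1, 0, +1), `mean_signed_lfc`
#'   and `n_genes`.
#' @export
mean_fc_vector <- function(overlap, table, treatment) {
  sub <- table[table$treatment == treatment & table$gene %in% overlap, ]
  if (nrow(sub) == 0)
    return(list(magnitude = NA_real_, direction = 0,
                mean_signed_lfc = NA_real_, n_genes = 0L))
  list(magnitude = mean(abs(sub$log2fc)),
       direction = sign(mean(sub$log2fc)),
       mean_signed_lfc = mean(sub$log2fc),
       n_genes = nrow(sub))
}

#' Enrichment of a catalog of pathways for one treatment
#'
#' Runs [select_deg()], then [fisher_enrichment()] and [mean_fc_vector()]
#' for every pathway. Raw right-tail p values are the headline statistic
#' (reported as -log10 p); Benjamini-Hochberg q-values across the tested
#' pathways are attached alongside.
#'
#' @param table DEG table.
#' @param catalogs a `gene_set_catalog` (or plain named list of gene sets).
#' @param treatment treatment label.
#' @param universe background genes; default all genes in the table.
#' @param ... thresholds passed to [select_deg()].
#' @return data.frame with one row per pathway: `pathway`, `overlap`, `p`,
#'   `minus_log10_p`, `q_bh`, `magnitude`, `direction`, `n_genes`,
#'   `pathway_size`.
#' @export
enrich_all <- function(table, catalogs, treatment,
                       universe = unique(table$gene), ...) {
  selected <- intersect(select_deg(table, treatment, ...), universe)
  rows <- lapply(names(catalogs), function(nm) {
    fe <- fisher_enrichment(selected, catalogs[[nm]], universe)
    fc <- mean_fc_vector(fe$overlap_genes, table, treatment)
    data.frame(pathway = nm, overlap = fe$overlap, p = fe$p,
               minus_log10_p = fe$minus_log10_p,
               magnitude = fc$magnitude, direction = fc$direction,
               n_genes = fc$n_genes, pathway_size = fe$pathway_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out[, c("pathway", "overlap", "p", "minus_log10_p", "q_bh", "magnitude",
          "direction", "n_genes", "pathway_size")]
}
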