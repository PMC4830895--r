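#' Simulate a differential-expression table with planted gene blocks
#'
#' Emulates the structure of a compound x gene differential-expression
#' compendium in which antioxidant-response (Nrf2 target) genes are induced by
#' severe hepatotoxicants while NF-kB-dependent inflammatory genes are induced
#' by cytokine model treatments and suppressed by the same hepatotoxicants.
#' Treatments are labelled `control`, `model_oxidative`, `model_inflammatory`,
#' `dili_severe` and `dili_mild`; genes belong to `nrf2_block`, `nfkb_block`
#' or `background`.
#'
#' Block-specific mean log2 fold changes (`effect_nrf2`, `effect_nfkb`) are
#' applied with additive Gaussian noise `lfc_noise_sd`:
#' \itemize{
#'   \item `model_oxidative`: +effect_nrf2 on `nrf2_block`
#'   \item `model_inflammatory`: +effect_nfkb on `nfkb_block`
#'   \item `dili_severe`: +effect_nrf2 on `nrf2_block`, -effect_nfkb on
#'     `nfkb_block`
#'   \item `dili_mild`: half-strength `dili_severe` pattern
#'   \item `control`: no planted effect anywhere
#' }
#' Adjusted p-values are a deterministic monotone function of the planted
#' signal-to-noise ratio |lfc| / `lfc_noise_sd` (two-sided normal tail, jittered
#' multiplicatively on the log scale), not a replicate-level model fit: this
#' module consumes differential-expression results, it does not produce them.
#' Average log2 expression is drawn high (around `expr_mean`) for block genes
#' and treatment-responsive conditions so that planted genes pass expression
#' filters, with background genes spanning a wider range.
#'
#' @param cfg a [sim_config()]; `cfg$seed` fixes all draws.
#' @param n_genes_per_block genes in each planted block.
#' @param n_background unplanted genes.
#' @param effect_nrf2,effect_nfkb planted mean |log2 fold change| of each block.
#' @param lfc_noise_sd Gaussian noise s.d. on every log2 fold change (0 gives a
#'   noiseless table).
#' @param expr_mean mean average-expression (log2) of planted block genes.
#' @return List with `table`, a data.frame with columns `gene`, `treatment`,
#'   `treatment_class`, `log2fc`, `adj_p`, `avg_expr`, and `blocks`, the
#'   planted gene -> block map (named character vector).
#' @export
#' @examples
#' deg <- simulate_deg_table(sim_config(seed = 7), n_genes_per_block = 5,
#'                           n_background = 10)
#' head(deg$table)
simulate_deg_table <- function(cfg,
                               n_genes_per_block = 40L,
                               n_background = 120L,
                               effect_nrf2 = 3,
                               effect_nfkb = 3.5,
                               lfc_noise_sd = 0.4,
                               expr_mean = 8) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 40L)
  genes <- c(sprintf("NRF2T%03d", seq_len(n_genes_per_block)),
             sprintf("NFKBT%03d", seq_len(n_genes_per_block)),
             sprintf("BG%04d", seq_len(n_background)))
  blocks <- stats::setNames(
    rep(c("nrf2_block", "nfkb_block", "background"),
        c(n_genes_per_block, n_genes_per_block, n_background)), genes)
  treatments <- data.frame(
    treatment = c("control", "model_oxidative", "model_inflammatory",
                  "dili_severe", "dili_mild"),
    treatment_class = c("control", "model_oxidative", "model_inflammatory",
                        "dili", "dili"),
    stringsAsFactors = FALSE)
  mean_lfc <- function(block, treatment) {
    switch(treatment,
      model_oxidative = if (block == "nrf2_block") effect_nrf2 else 0,
      model_inflammatory = if (block == "nfkb_block") effect_nfkb else 0,
      dili_severe = if (block == "nrf2_block") effect_nrf2
                    else if (block == "nfkb_block") -effect_nfkb else 0,
      dili_mild = if (block == "nrf2_block") effect_nrf2 / 2
                  else if (block == "nfkb_block") -effect_nfkb / 2 else 0,
      0)
  }
  tab <- expand.grid(gene = genes, treatment = treatments$treatment,
                     stringsAsFactors = FALSE)
  tab$treatment_class <-
    treatments$treatment_class[match(tab$treatment, treatments$treatment)]
  mu <- mapply(function(g, tr) mean_lfc(blocks[[g]], tr),
               tab$gene, tab$treatment)
  tab$log2fc <- mu +
    if (lfc_noise_sd > 0) stats::rnorm(nrow(tab), sd = lfc_noise_sd) else 0
  # deterministic monotone p-value: two-sided normal tail of |lfc|/noise,
  # jittered on the log10 scale
  sn <- abs(tab$log2fc) / max(lfc_noise_sd, 0.25)
  p <- 2 * stats::pnorm(-sn)
  jit <- stats::runif(nrow(tab), -0.2, 0.2)
  tab$adj_p <- pmin(1, pmax(10^(log10(p) * (1 + jit)), 1e-16))
  base_expr <- stats::setNames(
    c(stats::rnorm(2 * n_genes_per_block, expr_mean, 0.8),
      stats::runif(n_background, 2, 12)), genes)
  tab$avg_expr <- base_expr[tab$gene] + stats::rnorm(nrow(tab), 0, 0.3)
  rownames(tab) <- NULL
  list(table = tab[, c("gene", "treatment", "treatment_class",
                       "log2fc", "adj_p", "avg_expr")],
       blocks = blocks)
}

#' Write / read a differential-expression table as TSV
#'
#' @param table a DEG table as produced by [simulate_deg_table()].
#' @param path file path.
#' @return `write_deg_table` returns `path` invisibly; `read_deg_table`
#'   returns a data.frame.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "treatment", "log2fc", "adj_p", "avg_expr")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_deg_table: missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$adj_p < 0 | tab$adj_p > 1))
    stop("read_deg_table: adj_p outside [0, 1]")
  if (anyDuplicated(tab[, c("gene", "treatment")]))
    stop("read_deg_table: duplicate (gene, treatment) keys")
  tab
}
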