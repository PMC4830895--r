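#' Published per-drug assay summary
#'
#' Loads the summary of DILI-compound modulation of Nrf2 and NF-kB signaling
#' across the three live-cell assays: Srxn1-GFP fold induction (Nrf2
#' response), the delay of the second NF-kB nuclear translocation event upon
#' TNFa, and the Annexin-V apoptosis readout with and without 16 h of TNFa
#' co-exposure, plus the resulting percentage-point synergy.
#'
#' @return data.frame with columns `drug`, `abbrev`, `fold_induction`,
#'   `nfkb_delay_min`, `pct_dead`, `pct_dead_tnf`, `pct_increase`; one row
#'   per drug (15 compounds).
#' @export
#' @examples
#' d <- dili_summary()
#' with(d, all.equal(pct_increase, tnf_synergy(pct_dead, pct_dead_tnf)))
dili_summary <- function() {
  path <- system.file("extdata", "dili_summary.tsv", package = "hepadyn",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
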