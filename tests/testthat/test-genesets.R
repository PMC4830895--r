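test_that("catalog unions deduplicate and preserve provenance", {
  a <- gene_set_catalog(list(s1 = c("A", "B", "C")), source = "db1")
  b <- gene_set_catalog(list(s2 = c("B", "C", "D")), source = "db2")
  u <- union_catalog(list(a, b), category = "oxidative")
  expect_equal(u$gene, c("A", "B", "C", "D"))
  expect_equal(u$sources[u$gene == "B"], "db1,db2")
  expect_equal(u$sources[u$gene == "A"], "db1")
  # disjoint sets of sizes 3 and 4
  d1 <- gene_set_catalog(list(x = c("G1", "G2", "G3")), "d1")
  d2 <- gene_set_catalog(list(y = c("H1", "H2", "H3", "H4")), "d2")
  expect_equal(nrow(union_catalog(list(d1, d2))), 7)
  # identical sets collapse
  expect_equal(nrow(union_catalog(list(a, a))), 3)
})

test_that("gene sets round-trip through GMT", {
  sets <- list(NRF2_TARGETS = c("SRXN1", "GCLM", "HMOX1"),
               NFKB_TARGETS = c("CXCL1", "CCL2", "BCL2A1", "CXCL2"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f, source = "test")
  expect_equal(back$NRF2_TARGETS, sets$NRF2_TARGETS)
  expect_equal(back$NFKB_TARGETS, sets$NFKB_TARGETS)
  expect_equal(attr(back, "source"), "test")
})

test_that("the responsiveness filter applies its thresholds inclusively", {
  tab <- toy_deg_table()
  kept <- filter_responsive(tab, paste0("G", 1:6), filter_spec(),
                            category = "oxidative")
  expect_setequal(kept, c("G1", "G3", "G6"))
  # genes absent from the table are dropped with a warning
  expect_warning(
    kept2 <- filter_responsive(tab, c("G1", "NOPE"), filter_spec(),
                               category = "oxidative"),
    "absent")
  expect_equal(kept2, "G1")
  # inflammatory category raises the fold-change bar to 2.0
  kept_inf <- filter_responsive(tab, paste0("G", 1:6), filter_spec(),
                                category = "inflammatory")
  expect_setequal(kept_inf, "G3")
  expect_error(filter_responsive(tab, "G1", filter_spec(), "bogus"),
               "unknown category")
})

test_that("raising any filter threshold never enlarges the survivor set", {
  deg <- simulate_deg_table(sim_config(seed = 33), n_genes_per_block = 20,
                            n_background = 60)
  genes <- unique(deg$table$gene)
  base_spec <- filter_spec()
  base <- filter_responsive(deg$table, genes, base_spec, "oxidative")
  harder <- list(
    filter_spec(adj_p_max = 0.01),
    filter_spec(avg_expr_min = 7),
    filter_spec(abs_lfc_min = c(oxidative = 2.5, inflammatory = 2.0)))
  for (sp in harder) {
    kept <- filter_responsive(deg$table, genes, sp, "oxidative")
    expect_true(all(kept %in% base))
  }
})

test_that("DEG selection uses inclusive bounds on all three thresholds", {
  tab <- data.frame(gene = c("A", "B", "C"), treatment = "t",
                    log2fc = c(1.3, -1.4, 2.0), adj_p = c(0.05, 0.01, 0.2),
                    avg_expr = c(7, 8, 9))
  expect_setequal(select_deg(tab, "t"), c("A", "B"))
  expect_equal(select_deg(tab[0, ], "t"), character(0))
})

test_that("Fisher enrichment equals the exact combinatorial tail sum", {
  # spec'd worked instance: universe 100, pathway 20, selected 10, overlap 5
  uni <- sprintf("g%03d", 1:100)
  pathway <- uni[1:20]
  selected <- c(uni[1:5], uni[90:94])
  fe <- fisher_enrichment(selected, pathway, uni)
  expect_equal(fe$overlap, 5)
  expect_equal(fe$p, oracle_hyper_tail(5, 20, 100, 10), tolerance = 1e-12)
  # randomized instances across universes up to 200
  set.seed(11)
  for (i in 1:50) {
    u <- sample(20:200, 1)
    uni <- sprintf("u%03d", seq_len(u))
    m <- sample.int(u, 1)
    s <- sample.int(u, 1)
    pathway <- sample(uni, m)
    selected <- sample(uni, s)
    fe <- fisher_enrichment(selected, pathway, uni)
    expect_equal(fe$p,
                 oracle_hyper_tail(fe$overlap, m, u, s), tolerance = 1e-10)
  }
})

test_that("degenerate enrichment cases hit the tail boundaries", {
  uni <- letters[1:10]
  no_overlap <- fisher_enrichment(uni[1:3], uni[8:10], uni)
  expect_equal(no_overlap$p, 1)            # P(X >= 0) = 1
  whole <- fisher_enrichment(uni[1:4], uni, uni)
  expect_equal(whole$p, 1)                 # pathway = universe
  expect_error(fisher_enrichment("a", "a", character(0)), "empty universe")
  expect_error(fisher_enrichment("zz", uni[1:2], uni), "subset")
})

test_that("mean fold-change vectors encode magnitude and direction", {
  tab <- data.frame(gene = c("A", "B"), treatment = "t",
                    log2fc = c(2, 2), adj_p = 0.01, avg_expr = 8)
  v <- mean_fc_vector(c("A", "B"), tab, "t")
  expect_equal(v$magnitude, 2)
  expect_equal(v$direction, 1)
  tab$log2fc <- c(2, -2)
  v2 <- mean_fc_vector(c("A", "B"), tab, "t")
  expect_equal(v2$magnitude, 2)
  expect_equal(v2$direction, 0)            # balanced: drawn flat
  tab$log2fc <- c(-1, -3)
  v3 <- mean_fc_vector(c("A", "B"), tab, "t")
  expect_equal(v3$magnitude, 2)
  expect_equal(v3$direction, -1)
})

test_that("noiseless planted blocks cluster perfectly at k = 2", {
  skip_if_not_installed("mclust")
  deg <- simulate_deg_table(sim_config(seed = 44), n_genes_per_block = 15,
                            n_background = 0, lfc_noise_sd = 0)
  genes <- names(deg$blocks)
  cl <- cluster_heatmap(deg$table, genes, k = 2)
  ari <- mclust::adjustedRandIndex(cl$gene_clusters[genes],
                                   deg$blocks[genes])
  expect_equal(ari, 1)
})

test_that("identical rows merge first at distance zero", {
  tab <- data.frame(
    gene = rep(c("A", "B", "C"), each = 2),
    treatment = rep(c("t1", "t2"), 3),
    log2fc = c(1, 2, 1, 2, 5, 9), adj_p = 0.01, avg_expr = 8)
  cl <- cluster_heatmap(tab, c("A", "B", "C"), k = 2)
  expect_equal(cl$gene_tree$height[1], 0)
  expect_equal(cl$gene_clusters[["A"]], cl$gene_clusters[["B"]])
})

test_that("shuffling input gene order leaves the tree topology unchanged", {
  deg <- simulate_deg_table(sim_config(seed = 45), n_genes_per_block = 10,
                            n_background = 10)
  genes <- unique(deg$table$gene)
  cl1 <- cluster_heatmap(deg$table, genes, k = 3)
  set.seed(1)
  cl2 <- cluster_heatmap(deg$table, sample(genes), k = 3)
  expect_equal(sort(cl1$gene_tree$height), sort(cl2$gene_tree$height))
  # cophenetic ultrametrics agree gene-for-gene, so the topology is the same
  co1 <- as.matrix(stats::cophenetic(cl1$gene_tree))
  co2 <- as.matrix(stats::cophenetic(cl2$gene_tree))
  expect_equal(co1[genes, genes], co2[genes, genes])
})

test_that("missing fold changes are imputed as zero with a warning", {
  tab <- data.frame(gene = c("A", "A", "B"), treatment = c("t1", "t2", "t1"),
                    log2fc = c(1, 2, 3), adj_p = 0.01, avg_expr = 8)
  expect_warning(cl <- cluster_heatmap(tab, c("A", "B"), k = 2), "imputed")
  expect_equal(cl$matrix["B", "t2"], 0)
})

test_that("the planted pathway outcompetes random gene sets of equal size", {
  deg <- simulate_deg_table(sim_config(seed = 46))
  nrf2_genes <- names(deg$blocks)[deg$blocks == "nrf2_block"]
  universe <- unique(deg$table$gene)
  selected <- select_deg(deg$table, "dili_severe")
  p_planted <- fisher_enrichment(selected, nrf2_genes, universe)$p
  set.seed(2)
  wins <- sum(vapply(1:100, function(i) {
    rnd <- sample(universe, length(nrf2_genes))
    p_planted < fisher_enrichment(selected, rnd, universe)$p
  }, logical(1)))
  expect_gte(wins, 95)
})

test_that("the threshold sweep is monotone non-increasing in gene count", {
  deg <- simulate_deg_table(sim_config(seed = 47), n_genes_per_block = 20,
                            n_background = 40)
  sw <- sweep_lfc_threshold(deg$table, unique(deg$table$gene))
  expect_true(all(diff(sw$n_genes) <= 0))
})
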