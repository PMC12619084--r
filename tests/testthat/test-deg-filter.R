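make_tiny_experiment <- function(seed = 1, n_genes = 60) {
  cfg <- sim_expression_config(
    n_genes = n_genes, n_per_group = 3,
    deg_log2fc = c(g00003 = 2, g00007 = -2, g00011 = 1.5),
    enrich_ratio = c(g00003 = 4, g00005 = 8, g00011 = 0.5),
    noise_cv = 0.1, seed = seed)
  simulate_trap_tables(cfg)
}

test_that("boundary semantics follow the filter wording exactly", {
  samples <- data.frame(sample_id = paste0("s", 1:3),
                        condition = "control", fraction = "IP")
  m <- rbind(gA = c(1.0, 5, 5),     # exactly 1.0 in one sample
             gB = c(1.01, 5, 5),
             gC = c(0, 5, 5))
  tbl <- fpkm_table(m, samples)
  expect_identical(expressed_genes(tbl), "gB")   # strict > 1

  st <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   log2fc = c(1.0, 0, -1.0, 2),
                   adj_p = c(0.049, 0.001, 0.05, 0.051))
  degs <- call_degs(st, expressed = st$gene_id)
  # log2FC = 1.0 with p = 0.049: in (inclusive fold change, strict p)
  expect_identical(degs$gene_id, "gA")
  expect_identical(degs$direction, "up")

  ip <- fpkm_table(rbind(g1 = rep(4, 3), g2 = rep(4.2, 3),
                         g3 = rep(2, 3)),
                   samples)
  inp <- fpkm_table(rbind(g1 = rep(2, 3), g2 = rep(2, 3), g3 = rep(2, 3)),
                    data.frame(sample_id = paste0("t", 1:3),
                               condition = "control", fraction = "input"))
  enr <- astrocyte_enrichment(c("g1", "g2", "g3"), ip, inp)
  expect_identical(enr$enriched, c(FALSE, TRUE, FALSE))  # 2.0 is not "more than 2"
  # the >= variant is available for the figure-caption convention
  enr2 <- astrocyte_enrichment("g1", ip, inp, comparator = ">=")
  expect_true(enr2$enriched)
})

test_that("planted truth passes through the statistics table", {
  sim <- make_tiny_experiment()
  st <- sim$de_stats
  expect_identical(st$log2fc[st$gene_id == "g00011"], 1.5)
  expect_true(all(st$adj_p[sim$truth$is_deg] < 0.05))
  expect_true(all(st$adj_p[!sim$truth$is_deg] >= 0.05))
  # no planted DEGs -> empty call
  empty_cfg <- sim_expression_config(n_genes = 30, seed = 2)
  es <- simulate_trap_tables(empty_cfg)
  expect_identical(nrow(call_degs(es$de_stats,
                                  expressed_genes(es$ip))), 0L)
})

test_that("every filter equals the brute-force row scan on small tables", {
  for (seed in 1:5) {
    sim <- make_tiny_experiment(seed)
    oracle <- brute_filter_chain(sim$ip, sim$input, sim$de_stats)
    expressed <- expressed_genes(sim$ip)
    expect_identical(expressed, oracle$expressed)
    degs <- call_degs(sim$de_stats, expressed)
    expect_identical(degs$gene_id, oracle$degs)
    enr <- astrocyte_enrichment(degs$gene_id, sim$ip, sim$input)
    expect_identical(enr$gene_id[enr$enriched], oracle$enriched)
  }
})

test_that("filter stages nest and tighten monotonically", {
  sim <- make_tiny_experiment(9)
  expressed <- expressed_genes(sim$ip)
  degs <- call_degs(sim$de_stats, expressed)
  enr <- astrocyte_enrichment(degs$gene_id, sim$ip, sim$input)
  enriched <- enr$gene_id[enr$enriched]
  expect_true(all(enriched %in% degs$gene_id))
  expect_true(all(degs$gene_id %in% expressed))
  # raising any threshold never enlarges the surviving set
  for (fm in c(1, 2, 5))
    expect_true(all(expressed_genes(sim$ip, fpkm_min = fm) %in%
                      expressed_genes(sim$ip, fpkm_min = 1)))
  for (lf in c(1, 1.6, 2.5))
    expect_true(all(call_degs(sim$de_stats, expressed,
                              lfc_min = lf)$gene_id %in% degs$gene_id))
  n_at <- vapply(c(2, 3, 6), function(rt)
    sum(astrocyte_enrichment(degs$gene_id, sim$ip, sim$input,
                             ratio_threshold = rt)$enriched), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("planted enrichment ratios are recovered by Monte Carlo", {
  ratios <- vapply(1:100, function(seed) {
    cfg <- sim_expression_config(n_genes = 40, n_per_group = 3,
                                 deg_log2fc = c(g00002 = 2),
                                 enrich_ratio = c(g00002 = 4),
                                 noise_cv = 0.1, seed = seed)
    sim <- simulate_trap_tables(cfg)
    astrocyte_enrichment("g00002", sim$ip, sim$input)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4) / 4, 0.2)   # Monte-Carlo mean on target
  expect_gte(mean(abs(ratios - 4) / 4 < 0.2), 0.98)
})

test_that("top-k ranking is deterministic with documented tie-breaks", {
  degs <- data.frame(
    gene_id = c("gB", "gA", "gC", "gD", "gE"),
    log2fc = c(2, 2, 3, -4, 1.2),
    adj_p = c(0.01, 0.001, 0.02, 0.001, 0.03),
    direction = c("up", "up", "up", "down", "up"))
  top <- rank_top_degs(degs, k = 10, direction = "up")
  expect_identical(nrow(top), 4L)             # k larger than table: all
  expect_identical(top$gene_id, c("gC", "gA", "gB", "gE"))  # tie by adj_p
  tie <- data.frame(gene_id = c("gZ", "gY"), log2fc = c(2, 2),
                    adj_p = c(0.01, 0.01), direction = "up")
  expect_identical(rank_top_degs(tie, 2, "up")$gene_id, c("gY", "gZ"))
  down <- rank_top_degs(degs, 10, "down")
  expect_identical(down$gene_id, "gD")
  expect_error(rank_top_degs(degs, k = 0), "positive")
  # brute-force sort oracle on a planted ladder
  ladder <- data.frame(gene_id = sprintf("g%02d", 1:9),
                       log2fc = seq(1, 5, by = 0.5),
                       adj_p = rep(0.01, 9), direction = "up")
  expect_identical(rank_top_degs(ladder, 4, "up")$gene_id,
                   ladder$gene_id[order(-ladder$log2fc)][1:4])
})

test_that("marker panels report IP/input ratios per cell type", {
  cfg <- sim_expression_config(
    n_genes = 30, n_per_group = 3,
    enrich_ratio = c(g00001 = 5, g00002 = 5, g00003 = 5,
                     g00004 = 0.2, g00005 = 0.2),
    noise_cv = 0.1, seed = 4)
  sim <- simulate_trap_tables(cfg)
  panels <- list(astrocyte = c("g00001", "g00002", "g00003"),
                 neuron = c("g00004", "g00005"))
  r <- marker_enrichment_ratios(sim$ip, sim$input, panels)
  expect_lt(abs(r[["astrocyte"]] - 5) / 5, 0.15)
  expect_lt(abs(r[["neuron"]] - 0.2) / 0.2, 0.15)
  # permutation symmetry within a panel
  r2 <- marker_enrichment_ratios(sim$ip, sim$input,
                                 list(astrocyte = c("g00003", "g00001",
                                                    "g00002")))
  expect_equal(r2[["astrocyte"]], r[["astrocyte"]], tolerance = 1e-12)
  expect_error(marker_enrichment_ratios(sim$ip, sim$input,
                                        list(empty = character(0))),
               "empty")
})

test_that("release-concentration arithmetic scales the total range", {
  expect_equal(estimate_release_concentration(370, 560, 0.05),
               c(low = 18.5, high = 28))
  expect_equal(estimate_release_concentration(370, 560, 0),
               c(low = 0, high = 0))
  expect_equal(estimate_release_concentration(370, 560, 1),
               c(low = 370, high = 560))
  expect_error(estimate_release_concentration(-1, 5, 0.5), "non-negative")
  expect_error(estimate_release_concentration(10, 5, 0.5), "exceed")
  expect_error(estimate_release_concentration(1, 5, 1.5), "0, 1")
})

test_that("FPKM tables round-trip through TSV", {
  sim <- make_tiny_experiment(3, n_genes = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm_table(sim$ip, path)
  back <- read_fpkm_table(path)
  expect_equal(back$fpkm, sim$ip$fpkm, tolerance = 1e-9)
  expect_identical(back$samples$fraction, sim$ip$samples$fraction)
})
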