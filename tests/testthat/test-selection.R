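test_that("hotspot test reproduces the direct Poisson tail computation", {
  # M = 100 mutations total, 3 landing in a 1000-bp gene of a 1e6-bp genome
  genes <- toy_genes(1, 1000, gene_id = "gA")
  rec100 <- mutation_records("p1", "chr1", 1:100, "A", "G")
  rec100$contig <- c(rep("chr", 3), rep("chr2", 97))
  rec100$pos <- c(10L, 500L, 900L, seq_len(97))
  genes2 <- rbind(genes, toy_genes(1, 999000, gene_id = "rest",
                                   contig = "chr2"))
  out2 <- gene_hit_test(rec100, genes2, total_sites = 1e6)
  gA <- out2[out2$gene_id == "gA", ]
  expect_equal(gA$expected, 0.1)
  expect_equal(gA$observed, 3)
  direct_tail <- 1 - stats::ppois(2, 0.1)
  expect_equal(gA$p_raw, direct_tail, tolerance = 1e-12)
  expect_equal(gA$p_raw, 1.546531e-4, tolerance = 1e-6)
  # with a 4000-gene Bonferroni family the example p_adj is 0.619
  expect_equal(min(1, gA$p_raw * 4000), 0.6186123, tolerance = 1e-6)
})

test_that("genes with zero observed hits get p_raw 1", {
  genes <- toy_genes(c(1, 2001), c(2000, 4000))
  rec <- mutation_records("p1", "chr", c(5L, 10L), "A", "G")
  out <- gene_hit_test(rec, genes, total_sites = 4000)
  expect_equal(out$p_raw[out$gene_id == "g02"], 1)
  expect_equal(attr(out, "family_size"), 2L)
  out_t <- gene_hit_test(rec, genes, total_sites = 4000, family = "tested")
  expect_equal(attr(out_t, "family_size"), 1L)
})

test_that("allele-frequency filtering is strict and idempotent", {
  rec <- mutation_records("p1", "chr", 1:4, "A", "G",
                          allele_frequency = c(0.04, 0.05, 0.051, 0.5))
  kept <- filter_population_variants(rec, 0.05)
  expect_equal(kept$allele_frequency, c(0.051, 0.5))
  expect_identical(filter_population_variants(kept, 0.05), kept)
  empty <- rec[0, ]
  expect_equal(nrow(filter_population_variants(empty, 0.05)), 0L)
  expect_equal(nrow(filter_population_variants(rec, 0)), 4L)
  rec$allele_frequency[1] <- NA
  expect_error(filter_population_variants(rec, 0.05), "missing")
})

test_that("mean allele frequency per gene averages across populations", {
  genes <- toy_genes(c(10, 200), c(100, 300))
  meta <- data.frame(sample = c("p1", "p2"), group = "treatment")
  rec <- mutation_records(c("p1", "p2"), "chr", c(50L, 60L), "A", "G",
                          allele_frequency = c(0.2, 0.6))
  tab <- mean_allele_frequency_by_gene(rec, genes, meta)
  expect_equal(tab$mean_freq[tab$gene_id == "g01"], 0.4)
  expect_equal(tab$n_sites[tab$gene_id == "g01"], 2L)
  expect_false("g02" %in% tab$gene_id)   # no variants -> absent
  # intergenic sites are assigned a nearest-gene pseudo-label
  rec2 <- mutation_records("p1", "chr", 160L, "A", "G",
                           allele_frequency = 0.3)
  tab2 <- mean_allele_frequency_by_gene(rec2, genes, meta)
  expect_equal(tab2$gene_id, "intergenic:g02")  # 160 is nearer g02 (200-300)
})

test_that("Ka/Ks reproduces hand arithmetic and handles zero-syn genes", {
  opp <- structure(list(
    per_gene = data.frame(
      gene_id = c("gA", "gB", "gC", "gD"),
      syn_sites = c(250, 100, 300, 200),
      nonsyn_sites = c(750, 300, 900, 600),
      length_bp = c(1000, 400, 1200, 800)),
    at_sites = 0, gc_sites = 0,
    fourfold = data.frame()), class = "site_opportunities")
  rec <- mutation_records("p1", "chr", 1:8, "A", "G",
                          allele_frequency = 0.5)
  rec$gene_id <- c("gA", "gA", "gA", "gB", "gC", "gC", "gC", "gD")
  rec$effect <- c("nonsynonymous", "nonsynonymous", "synonymous",
                  "synonymous", "synonymous", "synonymous", "synonymous",
                  "nonsynonymous")
  out <- ka_ks(rec, opp)
  gA <- out[out$gene_id == "gA", ]
  expect_equal(gA$ka, 2 / 750)
  expect_equal(gA$ks, 1 / 250)
  expect_equal(gA$ka_ks, (2 / 750) / (1 / 250))
  expect_false(gA$calibrated)
  # zero nonsyn -> ratio 0
  expect_equal(out$ka_ks[out$gene_id == "gB"], 0)
  # gD has 0 synonymous hits -> calibrated pseudo-Ks
  gD <- out[out$gene_id == "gD", ]
  expect_true(gD$calibrated)
  slope <- sum(c(250, 100, 300) * c(1, 1, 3)) / sum(c(250, 100, 300)^2)
  expect_equal(gD$ks, max(0.5, slope * 200) / 200)
})

test_that("Ka/Ks is invariant to duplicating every population's records", {
  opp <- structure(list(
    per_gene = data.frame(gene_id = "gA", syn_sites = 250,
                          nonsyn_sites = 750, length_bp = 1000),
    at_sites = 0, gc_sites = 0, fourfold = data.frame()),
    class = "site_opportunities")
  rec <- mutation_records("p1", "chr", 1:3, "A", "G", allele_frequency = 0.5)
  rec$gene_id <- "gA"
  rec$effect <- c("nonsynonymous", "nonsynonymous", "synonymous")
  base <- ka_ks(rec, opp)
  dup <- rec
  dup$sample <- "p2"
  doubled <- ka_ks(rbind(rec, dup), opp)
  expect_equal(doubled$ka_ks, base$ka_ks)
})

test_that("through-origin calibration regression has its closed form", {
  expect_equal(
    calibrate_ks(data.frame(syn_sites = c(100, 300), syn_count = c(1, 3)),
                 200), 0.01)
  # identical calibration genes: slope is exactly count/sites
  expect_equal(
    calibrate_ks(data.frame(syn_sites = c(100, 100, 100),
                            syn_count = c(2, 2, 2)), 100), 0.02)
  # tiny target gene hits the half-count floor
  expect_equal(
    calibrate_ks(data.frame(syn_sites = c(100, 300), syn_count = c(1, 3)),
                 10), 0.05)
  expect_error(
    calibrate_ks(data.frame(syn_sites = 100, syn_count = 1), 50),
    "at least two")
})

test_that("aggregate Ka/Ks is near 1 for neutral simulated data", {
  set.seed(23)
  ref <- make_reference(length = 120000, n_genes = 300, gene_length = 300)
  sim <- simulate_ma(ref$genome, ref$genes, n_lines = 10,
                     bps_rate = 4e-6, indel_rate = 0,
                     divisions_per_transfer = 10, transfers = 10,
                     spectrum = uniform_spectrum())
  ann <- classify_mutations(sim$records, ref$genome, ref$genes)
  opp <- count_site_opportunities(ref$genome, ref$genes)
  out <- ka_ks(ann, opp)
  agg <- (sum(out$nonsyn_n) / sum(out$nonsyn_sites)) /
    (sum(out$syn_n) / sum(out$syn_sites))
  expect_gt(agg, 0.85)
  expect_lt(agg, 1.15)
})
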