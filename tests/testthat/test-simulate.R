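test_that("reference generation is seed-reproducible with the right layout", {
  ref1 <- make_reference(length = 10000, n_genes = 5, gene_length = 300,
                         seed = 99)
  ref2 <- make_reference(length = 10000, n_genes = 5, gene_length = 300,
                         seed = 99)
  expect_identical(ref1, ref2)
  expect_equal(nrow(ref1$genes), 5L)
  expect_true(all(ref1$genes$end - ref1$genes$start + 1 == 300))
  # non-overlapping
  o <- order(ref1$genes$start)
  expect_true(all(diff(ref1$genes$start[o]) >= 300))
  expect_error(make_reference(length = 1000, n_genes = 5,
                              gene_length = 300), "exceed")
})

test_that("realized GC content tracks the target at 100 kb", {
  ref <- make_reference(length = 100000, n_genes = 0, gc = 0.508, seed = 5)
  comp <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(ref$genome$seq), c("G", "C"))
  gc <- sum(comp) / 100000
  expect_lt(abs(gc - 0.508), 0.02 * 0.508)
})

test_that("MA simulation has Poisson event totals and exact metadata", {
  ref <- make_reference(length = 100000, n_genes = 0, seed = 17)
  sim <- simulate_ma(ref$genome, n_lines = 100, bps_rate = 1e-8,
                     indel_rate = 0, divisions_per_transfer = 100,
                     transfers = 10, seed = 17)
  # expected total 100 lines x 1e-8 * 1e5 * 1000 = 100; allow 5 sigma
  expect_gt(nrow(sim$records), 100 - 5 * 10)
  expect_lt(nrow(sim$records), 100 + 5 * 10)
  expect_equal(sim$metadata$T, rep(1000, 100))
  expect_equal(sim$metadata$N, rep(100000, 100))
  # zero rate -> zero mutations
  none <- simulate_ma(ref$genome, n_lines = 5, bps_rate = 0, indel_rate = 0,
                      divisions_per_transfer = 10, transfers = 1)
  expect_equal(nrow(none$records), 0L)
  # sparsity guard refuses multi-hit regimes
  expect_error(simulate_ma(ref$genome, n_lines = 2, bps_rate = 1e-3,
                           divisions_per_transfer = 100, transfers = 10),
               "multi-hit")
  # determinism
  sim2 <- simulate_ma(ref$genome, n_lines = 100, bps_rate = 1e-8,
                      indel_rate = 0, divisions_per_transfer = 100,
                      transfers = 10, seed = 17)
  expect_identical(sim, sim2)
})

test_that("simulated spectrum recovers the configured class probabilities", {
  ref <- make_reference(length = 100000, n_genes = 0, gc = 0.5, seed = 21)
  spec <- default_spectrum()
  sim <- simulate_ma(ref$genome, n_lines = 10, bps_rate = 1e-5,
                     indel_rate = 0, divisions_per_transfer = 100,
                     transfers = 10, spectrum = spec, seed = 21)
  ann <- classify_mutations(sim$records, ref$genome,
                            toy_genes(integer(), integer())[0, ])
  n <- nrow(ann)
  expect_gt(n, 8000)          # ~1e4 mutations
  realized <- table(factor(ann$spectrum_class, levels = SPECTRUM_CLASSES)) / n
  for (cl in SPECTRUM_CLASSES) {
    se <- sqrt(spec[[cl]] * (1 - spec[[cl]]) / n)
    expect_lt(abs(realized[[cl]] - spec[[cl]]), 3 * se + 1e-9)
  }
})

test_that("neutral evolution without mutation yields no variants", {
  ref <- make_reference(length = 5000, n_genes = 2, gene_length = 300,
                        seed = 3)
  ev <- simulate_evolution(ref$genome, ref$genes, n_populations = 2,
                           mu = 0, transfers = 5, seed = 3)
  expect_equal(nrow(ev$records), 0L)
})

test_that("evolution output is seed-reproducible and threshold-filtered", {
  ref <- make_reference(length = 20000, n_genes = 10, gene_length = 300,
                        seed = 8)
  ev1 <- simulate_evolution(ref$genome, ref$genes, n_populations = 2,
                            mu = 1e-6, transfers = 8, seed = 8)
  ev2 <- simulate_evolution(ref$genome, ref$genes, n_populations = 2,
                            mu = 1e-6, transfers = 8, seed = 8)
  expect_identical(ev1, ev2)
  if (nrow(ev1$records) > 0) {
    expect_true(all(ev1$records$allele_frequency > 0.05))
    expect_true(all(ev1$records$ref != ev1$records$alt))
  }
})

test_that("plating counts are Poisson around eop x reference", {
  series <- simulate_plating(c(`0` = 0.5), reference_cfu = 1000,
                             replicates = 100, seed = 41)
  m <- mean(series$cfu)
  expect_lt(abs(m - 500), 5 * sqrt(500 / 100))
  # zero efficiency gives exactly zero counts, and the MIC drops out
  mic_series <- simulate_plating(
    c(`0` = 1, `20` = 0.4, `40` = 0.1, `60` = 0, `80` = 0),
    reference_cfu = 1000, replicates = 3, seed = 42)
  expect_true(all(mic_series$cfu[mic_series$concentration >= 60] == 0))
  expect_equal(mic_from_series(mic_series), 60)
  expect_error(simulate_plating(c(`0` = 1.5), 100), "\\[0, 1\\]")
})
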