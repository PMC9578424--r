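test_that("rate estimation reproduces hand arithmetic", {
  meta <- data.frame(sample = c("L1", "L2"), T = c(10, 5), N = c(100, 200),
                     group = "control")
  rec <- mutation_records(c("L1", "L1", "L2", "L2"), "chr", 1:4, "A", "G")
  est <- estimate_rate(rec, meta)
  expect_equal(est$denominator, 2000)
  expect_equal(est$rate, 2e-3)
  expect_equal(est$m, 4L)
  # brute-force quotient property on random designs
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    meta <- data.frame(sample = paste0("L", 1:n),
                       T = sample(5:50, n, replace = TRUE),
                       N = sample(100:1000, n, replace = TRUE))
    m <- sample(0:20, 1)
    rec <- if (m > 0) mutation_records(sample(meta$sample, m, replace = TRUE),
                                       "chr", seq_len(m), "A", "G")
           else mutation_records(character(), character(), integer(),
                                 character(), character())
    est <- estimate_rate(rec, meta)
    expect_equal(est$rate, m / sum(meta$N * meta$T))
  }
})

test_that("zero events give rate 0 with CI lower bound exactly 0", {
  meta <- data.frame(sample = "L1", T = 10, N = 100)
  est <- estimate_rate(mutation_records(character(), character(), integer(),
                                        character(), character()), meta)
  expect_equal(est$rate, 0)
  expect_equal(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
})

test_that("chi-square Poisson interval matches numeric tail inversion", {
  ci <- poisson_ci(4, 2000)
  oracle <- poisson_ci_oracle(4, 2000)
  expect_equal(unname(ci), unname(oracle), tolerance = 1e-8)
  # frozen oracle values
  expect_equal(unname(ci["low"]), 5.449327e-4, tolerance = 1e-6)
  expect_equal(unname(ci["high"]), 5.120794e-3, tolerance = 1e-6)
  for (m in c(1, 10, 105)) {
    expect_equal(unname(poisson_ci(m, 1)), unname(poisson_ci_oracle(m, 1)),
                 tolerance = 1e-8)
  }
  expect_error(poisson_ci(2.5, 1), "integer")
})

test_that("rate CI invariants hold", {
  est <- rate_from_counts(105, 142, 1099, 4641652)
  expect_true(est$ci_low <= est$rate && est$rate <= est$ci_high)
  expect_equal(est$rate, est$m / est$denominator)
})

test_that("conditional class rates scale by origin-pair site counts", {
  g <- toy_genome("ATATATGCGCGC")       # 6 A/T sites, 6 G/C sites
  opp <- count_site_opportunities(g, toy_genes(integer(), integer())[0, ])
  meta <- data.frame(sample = c("L1", "L2"), T = c(100, 100), N = 12)
  spec <- new_spectrum_counts(setNames(c(2L, 3L, 0L, 1L, 0L, 0L),
                                       SPECTRUM_CLASSES))
  out <- conditional_spectrum_rates(spec, opp, meta)
  expect_equal(out$rate[out$class == "A:T>G:C"], 2 / (6 * 200))
  expect_equal(out$rate[out$class == "G:C>A:T"], 3 / (6 * 200))
  # linearity: doubling counts doubles rates
  out2 <- conditional_spectrum_rates(
    new_spectrum_counts(setNames(c(4L, 6L, 0L, 2L, 0L, 0L),
                                 SPECTRUM_CLASSES)), opp, meta)
  expect_equal(out2$rate, 2 * out$rate)
  # BPS rate equals the opportunity-weighted average of class rates
  total_rate <- sum(spec$classes) / (12 * 200)
  expect_equal(sum(out$rate * out$origin_sites) / 12, total_rate)
})

test_that("4-fold degenerate rate uses the restricted site set", {
  ff <- data.frame(contig = "chr", pos = c(3L, 6L, 9L))
  meta <- data.frame(sample = paste0("L", 1:10), T = 100, N = 1000)
  rec <- mutation_records(c("L1", "L2"), "chr", c(3L, 100L), "G", "A")
  est <- fourfold_rate(rec, ff, meta)
  expect_equal(est$m, 1L)                       # only pos 3 is 4-fold
  expect_equal(est$denominator, 3 * 1000)
  expect_error(fourfold_rate(rec, ff[0, ], meta), "empty")
})

test_that("bottleneck effective size follows the harmonic-mean model", {
  expect_equal(effective_population_size(1), 1)
  expect_equal(effective_population_size(3), 3 / (1 + 1 / 2 + 1 / 4))
  expect_equal(round(effective_population_size(27.48)), 14)
  # monotone increasing in g, asymptotically g/2
  gs <- c(2, 5, 10, 20, 40, 80)
  nes <- vapply(gs, effective_population_size, numeric(1))
  expect_true(all(diff(nes) > 0))
  expect_equal(effective_population_size(1000), 500, tolerance = 1e-6)
  expect_error(effective_population_size(0), "positive")
})
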