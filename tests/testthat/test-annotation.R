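test_that("codon substitution gives the hand-derived effect and class", {
  g <- toy_genome("TTTGGG")
  genes <- toy_genes(1, 6)
  # TTT third position T>C: TTC is still Phe -> synonymous, class A:T>G:C
  rec <- classify_mutations(mutation_records("L1", "chr", 3, "T", "C"),
                            g, genes)
  expect_equal(rec$region, "coding")
  expect_equal(rec$effect, "synonymous")
  expect_equal(rec$spectrum_class, "A:T>G:C")
  # TTT first position T>G: GTT is Val -> nonsynonymous
  rec2 <- classify_mutations(mutation_records("L1", "chr", 1, "T", "G"),
                             g, genes)
  expect_equal(rec2$effect, "nonsynonymous")
})

test_that("positions outside genes are intergenic/noncoding", {
  g <- toy_genome("AAATTTGGGCCC")
  genes <- toy_genes(4, 9)
  rec <- classify_mutations(mutation_records("L1", "chr", 2, "A", "G"),
                            g, genes)
  expect_equal(rec$region, "intergenic")
  expect_equal(rec$effect, "noncoding")
  expect_true(is.na(rec$gene_id))
})

test_that("reference mismatches are flagged and reported, not dropped", {
  g <- toy_genome("AAAA")
  rec <- mutation_records("L1", "chr", 2, "G", "A")  # genome has A, not G
  expect_warning(out <- classify_mutations(rec, g, toy_genes(1, 3)),
                 "disagree")
  expect_equal(nrow(out), 1L)
  expect_true(out$ref_mismatch)
})

test_that("positions in two genes are labeled overlap with full attribution", {
  g <- toy_genome("ATGAAACCCGGGTTTTAA")
  genes <- toy_genes(c(1, 10), c(12, 18))
  rec <- classify_mutations(mutation_records("L1", "chr", 11, "G", "A"),
                            g, genes)
  expect_equal(rec$region, "overlap")
  expect_equal(rec$gene_id, "g01,g02")
})

test_that("minus-strand classification equals the plus-strand reverse complement", {
  set.seed(11)
  for (i in 1:20) {
    cds <- random_cds(6)
    gplus <- toy_genome(cds)
    gminus <- toy_genome(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds))))
    pos <- sample(18, 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    r_plus <- classify_mutations(
      mutation_records("L", "chr", pos, ref, alt),
      gplus, toy_genes(1, 18, strand = "+"))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    r_minus <- classify_mutations(
      mutation_records("L", "chr", 19 - pos, comp[[ref]], comp[[alt]]),
      gminus, toy_genes(1, 18, strand = "-"))
    expect_equal(r_minus$effect, r_plus$effect)
    expect_equal(r_minus$spectrum_class, r_plus$spectrum_class)
  }
})

test_that("spectrum class is invariant to the reporting strand", {
  ref <- c("A", "C", "G", "T")
  for (r in ref) {
    for (a in setdiff(ref, r)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      expect_equal(spectrum_class_of(r, a),
                   spectrum_class_of(comp[[r]], comp[[a]]))
    }
  }
})

test_that("site opportunities match hand-derived codon arithmetic", {
  # TTT: only TTT>TTC synonymous -> syn 1/3, nonsyn 8/3
  opp <- count_site_opportunities(toy_genome("TTT"), toy_genes(1, 3))
  expect_equal(opp$per_gene$syn_sites, 1 / 3)
  expect_equal(opp$per_gene$nonsyn_sites, 8 / 3)
  # GGG: third position fully degenerate -> syn 1, nonsyn 2; 4-fold at pos 3
  opp2 <- count_site_opportunities(toy_genome("GGG"), toy_genes(1, 3))
  expect_equal(opp2$per_gene$syn_sites, 1)
  expect_equal(opp2$per_gene$nonsyn_sites, 2)
  expect_equal(opp2$fourfold$pos, 3L)
  # sum rule: syn + nonsyn = 3 x codons
  expect_equal(opp2$per_gene$syn_sites + opp2$per_gene$nonsyn_sites, 3)
})

test_that("empty gene list still counts genome composition", {
  opp <- count_site_opportunities(toy_genome("AATTGGCCNN"),
                                  toy_genes(integer(), integer())[0, ])
  expect_equal(nrow(opp$per_gene), 0L)
  expect_equal(opp$at_sites, 4)
  expect_equal(opp$gc_sites, 4)    # Ns excluded
})

test_that("fractional site counts equal exhaustive enumeration for short CDSs", {
  set.seed(42)
  for (n_codons in c(1, 2, 5, 10)) {
    for (rep in 1:5) {
      cds <- random_cds(n_codons)
      oracle <- brute_force_sites(cds)
      opp <- count_site_opportunities(toy_genome(cds),
                                      toy_genes(1, nchar(cds)))
      expect_equal(opp$per_gene$syn_sites, unname(oracle["syn"]))
      expect_equal(opp$per_gene$nonsyn_sites, unname(oracle["nonsyn"]))
    }
  }
})

test_that("CDS with length not a multiple of 3 is skipped with a warning", {
  expect_warning(
    opp <- count_site_opportunities(toy_genome("TTTT"), toy_genes(1, 4)),
    "multiple of 3")
  expect_equal(nrow(opp$per_gene), 0L)
})

test_that("phase adjustment shifts the codon frame", {
  # with phase 1, codons start at position 2: TTG GGx on 'TTTGGG...' etc.
  g <- toy_genome("ATTTGGGA")
  genes <- toy_genes(1, 7, phase = 1L)
  opp <- count_site_opportunities(g, genes)
  expect_equal(opp$per_gene$syn_sites + opp$per_gene$nonsyn_sites, 6)
})

test_that("spectrum weighting changes apportionment as expected", {
  # weight everything onto A:T>G:C: at TTT's third position the only
  # substitution with weight is T>C, which is synonymous -> syn site = 1
  w <- setNames(c(1, 0, 0, 0, 0, 0), SPECTRUM_CLASSES)
  # give tiny mass to other classes to keep weights valid at G/C sites
  w[2:6] <- 1e-9
  opp <- count_site_opportunities(toy_genome("TTT"), toy_genes(1, 3), w)
  expect_equal(opp$per_gene$syn_sites, 1, tolerance = 1e-6)
})
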