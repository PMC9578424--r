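# In-code fixtures and independent oracles shared across the suite.

toy_genome <- function(seq, contig = "chr") {
  new_reference_genome(setNames(seq, contig))
}

toy_genes <- function(start, end, strand = "+", gene_id = NULL,
                      contig = "chr", phase = 0L) {
  n <- length(start)
  ids <- if (is.null(gene_id)) sprintf("g%02d", seq_len(n)) else
    rep_len(gene_id, n)
  data.frame(
    gene_id = ids, name = ids,
    contig = rep_len(contig, n), start = start, end = end,
    strand = rep_len(strand, n), is_cds = rep_len(TRUE, n),
    phase = rep_len(phase, n), stringsAsFactors = FALSE
  )
}

uniform_spectrum <- function() {
  setNames(rep(1 / 6, 6), SPECTRUM_CLASSES)
}

# Independent Nei-Gojobori oracle: exhaustive enumeration of the 9 possible
# substitutions per codon of a plus-strand CDS sequence (uniform weights).
brute_force_sites <- function(cds_seq) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n <- nchar(cds_seq)
  stopifnot(n %% 3 == 0)
  syn <- 0
  for (i in seq(1, n, 3)) {
    codon <- substr(cds_seq, i, i + 2)
    for (p in 1:3) {
      b <- substr(codon, p, p)
      n_syn <- 0
      for (a in setdiff(bases, b)) {
        mut <- codon
        substr(mut, p, p) <- a
        if (identical(code[[mut]], code[[codon]])) n_syn <- n_syn + 1
      }
      syn <- syn + n_syn / 3
    }
  }
  c(syn = syn, nonsyn = n - syn)
}

# Independent Poisson CI oracle: numeric inversion of the Poisson tail
# probabilities (no chi-square quantiles involved).
poisson_ci_oracle <- function(m, denominator, level = 0.95) {
  alpha <- (1 - level) / 2
  low <- if (m == 0) 0 else
    stats::uniroot(function(l) stats::ppois(m - 1, l, lower.tail = FALSE) -
                     alpha, c(1e-12, 10 * m + 50), tol = 1e-12)$root
  high <- stats::uniroot(function(l) stats::ppois(m, l) - alpha,
                         c(1e-12, 10 * m + 50), tol = 1e-12)$root
  c(low = low / denominator, high = high / denominator)
}

random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}
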