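# Six strand-collapsed base-substitution classes (2 transitions first).
SPECTRUM_CLASSES <- c("A:T>G:C", "G:C>A:T",
                      "A:T>T:A", "A:T>C:G", "G:C>C:G", "G:C>T:A")
TRANSITION_CLASSES <- SPECTRUM_CLASSES[1:2]

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# directed change -> collapsed class, keyed "<ref>><alt>"
.spectrum_lookup <- local({
  m <- c("A>G" = "A:T>G:C", "T>C" = "A:T>G:C",
         "G>A" = "G:C>A:T", "C>T" = "G:C>A:T",
         "A>T" = "A:T>T:A", "T>A" = "A:T>T:A",
         "A>C" = "A:T>C:G", "T>G" = "A:T>C:G",
         "G>C" = "G:C>C:G", "C>G" = "G:C>C:G",
         "G>T" = "G:C>T:A", "C>A" = "G:C>T:A")
  m
})

#' Collapsed spectrum class of a base substitution
#'
#' Complementary changes are collapsed (a G>A call equals a C>T call at the
#' complementary position), yielding the six classes used throughout the
#' package: two transitions (A:T>G:C, G:C>A:T) and four transversions.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @return Character vector of class labels; `NA` for N-containing calls.
#' @export
spectrum_class_of <- function(ref, alt) {
  unname(.spectrum_lookup[paste0(toupper(ref), ">", toupper(alt))])
}

#' Classify mutations by region, coding effect and spectrum class
#'
#' Base substitutions inside a CDS get a synonymous/nonsynonymous call by
#' substituting the mutant base into its codon (standard genetic code;
#' minus-strand genes are handled by complementing alleles). Positions inside
#' two or more genes are labeled `"overlap"` (they are attributed to every
#' overlapping gene in `gene_id`, comma-separated, for gene-level tests, but
#' excluded from the synonymous/nonsynonymous tally as in the study's
#' category table). Records whose stated reference allele disagrees with the
#' genome base are flagged (`ref_mismatch`), reported via a warning, and kept.
#'
#' @param records Mutation-record data.frame.
#' @param genome A `reference_genome`.
#' @param genes Gene-model data.frame (CDS rows are used for effects).
#' @return `records` with `region`, `effect`, `spectrum_class`, `gene_id` and
#'   `ref_mismatch` filled in.
#' @export
classify_mutations <- function(records, genome, genes) {
  genes <- validate_genes(genes, genome)
  if (nrow(records) == 0L) return(records)
  bad_contig <- !records$contig %in% names(genome$seq)
  if (any(bad_contig)) stop("record contig(s) not in genome: ",
                            paste(unique(records$contig[bad_contig]),
                                  collapse = ", "))
  outside <- records$pos < 1L | records$pos > genome$length[records$contig]
  if (any(outside)) stop(sum(outside), " record position(s) outside contig")

  hit_idx <- overlap_gene_index(records, genes)   # list of gene row indices
  n_hits <- lengths(hit_idx)
  records$region <- ifelse(n_hits == 0L, "intergenic",
                           ifelse(n_hits >= 2L, "overlap", "coding"))
  records$gene_id <- vapply(hit_idx, function(i)
    if (length(i)) paste(genes$gene_id[i], collapse = ",") else NA_character_,
    character(1))

  is_bps <- records$mclass == "BPS"
  records$spectrum_class <- NA_character_
  records$spectrum_class[is_bps] <-
    spectrum_class_of(records$ref[is_bps], records$alt[is_bps])

  # reference concordance (BPS only: indel anchors are caller-dependent)
  genome_base <- rep(NA_character_, nrow(records))
  genome_base[is_bps] <- mapply(genome_base_at, contig = records$contig[is_bps],
                                pos = records$pos[is_bps],
                                MoreArgs = list(genome = genome))
  records$ref_mismatch <- is_bps & !is.na(genome_base) &
    genome_base != records$ref
  if (any(records$ref_mismatch)) {
    warning(sum(records$ref_mismatch),
            " record(s) disagree with the genome reference base; ",
            "flagged in column 'ref_mismatch'")
  }

  records$effect <- ifelse(records$mclass == "BPS", NA_character_,
                           NA_character_)
  records$effect[is_bps & n_hits == 0L] <- "noncoding"
  code_rows <- which(is_bps & n_hits > 0L)
  for (i in code_rows) {
    g <- genes[hit_idx[[i]][1L], ]
    records$effect[i] <- codon_effect(genome, g, records$pos[i],
                                      records$ref[i], records$alt[i])
  }
  records
}

# row indices of CDS genes overlapping each record position
overlap_gene_index <- function(records, genes) {
  cds <- which(genes$is_cds)
  out <- vector("list", nrow(records))
  for (ct in unique(records$contig)) {
    gi <- cds[genes$contig[cds] == ct]
    ri <- which(records$contig == ct)
    if (!length(gi)) { out[ri] <- list(integer()); next }
    ir_g <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    ir_r <- IRanges::IRanges(records$pos[ri], records$pos[ri])
    ov <- IRanges::findOverlaps(ir_r, ir_g)
    sp <- split(gi[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    out[ri] <- list(integer())
    out[ri[as.integer(names(sp))]] <- sp
  }
  out
}

# synonymous/nonsynonymous call for a BPS inside one CDS gene; NA when the
# codon is incomplete (phase-trimmed head/tail) or contains N
codon_effect <- function(genome, gene, pos, ref, alt) {
  phase <- if (is.na(gene$phase)) 0L else gene$phase
  if (gene$strand == "+") {
    off <- pos - (gene$start + phase)
    if (off < 0L) return(NA_character_)
    idx <- off %/% 3L
    within <- off %% 3L + 1L
    cstart <- gene$start + phase + idx * 3L
    if (cstart + 2L > gene$end) return(NA_character_)
    codon <- substr(genome$seq[[gene$contig]], cstart, cstart + 2L)
    ref_c <- ref; alt_c <- alt
  } else {
    off <- (gene$end - phase) - pos
    if (off < 0L) return(NA_character_)
    idx <- off %/% 3L
    within <- off %% 3L + 1L
    hi <- gene$end - phase - idx * 3L
    if (hi - 2L < gene$start) return(NA_character_)
    codon <- revcomp(substr(genome$seq[[gene$contig]], hi - 2L, hi))
    ref_c <- COMP[[ref]]; alt_c <- COMP[[alt]]
  }
  if (grepl("N", codon) || ref_c == "N" || alt_c == "N") return(NA_character_)
  if (substr(codon, within, within) != ref_c) return(NA_character_)
  mut <- codon
  substr(mut, within, within) <- alt_c
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  aa1 <- Biostrings::GENETIC_CODE[[mut]]
  if (identical(aa0, aa1)) "synonymous" else "nonsynonymous"
}

#' Count mutational site opportunities
#'
#' Nei–Gojobori-style fractional synonymous/nonsynonymous site counts per
#' CDS: each codon position contributes one site, apportioned by the fraction
#' of its three possible substitutions that are synonymous, optionally
#' weighted by a six-class mutation spectrum (uniform by default, i.e. all 12
#' directed changes equally likely). Also tallies genome-wide A/T and G/C
#' site counts (N bases excluded) and the set of 4-fold degenerate
#' third-codon positions (all three alternative bases encode the same amino
#' acid).
#'
#' @param genome A `reference_genome`.
#' @param genes Gene-model data.frame; CDS rows whose phase-adjusted length
#'   is not a multiple of 3 are skipped with a warning.
#' @param spectrum_weights Optional named numeric over the six classes in
#'   [SPECTRUM_CLASSES] (need not sum to 1; only relative weights matter).
#' @return A `site_opportunities` list: `per_gene` (gene_id, syn_sites,
#'   nonsyn_sites, length_bp), `at_sites`, `gc_sites`, and `fourfold`
#'   (data.frame of contig/pos/gene_id).
#' @export
count_site_opportunities <- function(genome, genes, spectrum_weights = NULL) {
  genes <- validate_genes(genes, genome)
  comp <- genome_base_composition(genome)
  tabs <- codon_site_tables(spectrum_weights)

  cds <- genes[genes$is_cds, , drop = FALSE]
  per <- data.frame(gene_id = character(), syn_sites = numeric(),
                    nonsyn_sites = numeric(), length_bp = integer(),
                    stringsAsFactors = FALSE)
  ff <- list()
  for (k in seq_len(nrow(cds))) {
    g <- cds[k, ]
    phase <- if (is.na(g$phase)) 0L else g$phase
    len_bp <- g$end - g$start + 1L
    raw <- substr(genome$seq[[g$contig]], g$start, g$end)
    cod_seq <- if (g$strand == "+") substr(raw, phase + 1L, len_bp)
               else substr(revcomp(raw), phase + 1L, len_bp)
    n <- nchar(cod_seq)
    if (n %% 3L != 0L) {
      warning("skipping gene ", g$gene_id,
              ": CDS length not a multiple of 3 after phase adjustment")
      next
    }
    starts <- seq.int(1L, n, 3L)
    codons <- substring(cod_seq, starts, starts + 2L)
    known <- codons %in% rownames(tabs$syn_frac)
    syn <- sum(tabs$syn_frac[codons[known], , drop = FALSE])
    nonsyn <- 3 * sum(known) - syn
    per <- rbind(per, data.frame(gene_id = g$gene_id, syn_sites = syn,
                                 nonsyn_sites = nonsyn, length_bp = len_bp,
                                 stringsAsFactors = FALSE))
    ffi <- which(known & tabs$fourfold[codons])
    if (length(ffi)) {
      idx0 <- ffi - 1L
      gpos <- if (g$strand == "+") g$start + phase + idx0 * 3L + 2L
              else g$end - phase - idx0 * 3L - 2L
      ff[[length(ff) + 1L]] <- data.frame(contig = g$contig, pos = gpos,
                                          gene_id = g$gene_id,
                                          stringsAsFactors = FALSE)
    }
  }
  fourfold <- if (length(ff)) do.call(rbind, ff) else
    data.frame(contig = character(), pos = integer(), gene_id = character(),
               stringsAsFactors = FALSE)
  fourfold <- fourfold[!duplicated(paste(fourfold$contig, fourfold$pos)), ,
                       drop = FALSE]
  structure(list(per_gene = per,
                 at_sites = comp[["at_sites"]],
                 gc_sites = comp[["gc_sites"]],
                 fourfold = fourfold,
                 spectrum_weights = tabs$weights),
            class = "site_opportunities")
}

# per-codon lookup: synonymous site fraction at each of the 3 positions,
# and 4-fold degeneracy of the third position
codon_site_tables <- function(spectrum_weights = NULL) {
  if (is.null(spectrum_weights)) {
    w <- setNames(rep(1, 6), SPECTRUM_CLASSES)
  } else {
    if (!all(SPECTRUM_CLASSES %in% names(spectrum_weights)))
      stop("spectrum_weights must be named by the six classes")
    w <- spectrum_weights[SPECTRUM_CLASSES]
    if (any(w < 0) || sum(w) <= 0) stop("invalid spectrum weights")
  }
  codons <- rownames <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1,
                              paste, collapse = "")
  syn_frac <- matrix(0, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  fourfold <- setNames(logical(64), codons)
  for (cod in codons) {
    aa <- Biostrings::GENETIC_CODE[[cod]]
    for (p in 1:3) {
      b <- substr(cod, p, p)
      alts <- setdiff(BASES, b)
      wsub <- w[spectrum_class_of(rep(b, 3), alts)]
      muts <- vapply(alts, function(a) {
        m <- cod; substr(m, p, p) <- a; m
      }, character(1))
      syn <- vapply(muts, function(m)
        identical(Biostrings::GENETIC_CODE[[m]], aa), logical(1))
      syn_frac[cod, p] <- sum(wsub * syn) / sum(wsub)
      if (p == 3L) fourfold[cod] <- all(syn)
    }
  }
  list(syn_frac = syn_frac, fourfold = fourfold, weights = w / sum(w))
}

#' Neutral nonsynonymous-to-synonymous expectation
#'
#' Ratio of total nonsynonymous to total synonymous site opportunities,
#' the expected nonsyn:syn mutation-count ratio under strict neutrality.
#'
#' @param opportunities A `site_opportunities` object.
#' @return A single positive number.
#' @export
neutral_ns_ratio <- function(opportunities) {
  s <- sum(opportunities$per_gene$syn_sites)
  if (s <= 0) stop("no synonymous site opportunities")
  sum(opportunities$per_gene$nonsyn_sites) / s
}
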