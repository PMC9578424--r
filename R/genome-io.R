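#' Read a reference genome from a FASTA file
#'
#' Loads every contig of a (possibly multi-record) FASTA file into a
#' `reference_genome` object. Sequences are uppercased; contig order is
#' preserved; the alphabet is restricted to A, C, G, T and N.
#'
#' @param path Path to a FASTA file.
#' @return A `reference_genome`: a list with `seq` (named character vector of
#'   contig sequences) and `length` (named integer vector of contig lengths).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  s <- toupper(as.character(seqs))
  names(s) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("contig(s) with characters outside A/C/G/T/N: ",
         paste(names(s)[bad], collapse = ", "))
  }
  new_reference_genome(s)
}

#' Construct a reference genome from in-memory sequences
#'
#' @param seq Named character vector of contig sequences (A/C/G/T/N).
#' @return A `reference_genome` object.
#' @export
new_reference_genome <- function(seq) {
  stopifnot(is.character(seq), length(seq) > 0L)
  if (is.null(names(seq))) names(seq) <- paste0("contig_", seq_along(seq))
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) stop("alphabet restricted to A/C/G/T/N")
  structure(list(seq = seq, length = setNames(nchar(seq), names(seq))),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", length(x$seq), " contig(s), ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

# total A/C/G/T/N-resolved length (Ns excluded from site opportunities)
genome_sites <- function(genome) {
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(genome$seq), c("A", "C", "G", "T"))
  sum(freq)
}

genome_base_composition <- function(genome) {
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(genome$seq), c("A", "C", "G", "T"))
  tot <- colSums(freq)
  c(at_sites = unname(tot["A"] + tot["T"]),
    gc_sites = unname(tot["G"] + tot["C"]))
}

genome_base_at <- function(genome, contig, pos) {
  substr(genome$seq[[contig]], pos, pos)
}

#' Read gene models from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive exactly as in GFF3; strand is
#' preserved (no coordinate flipping for minus-strand genes). Only the
#' requested feature types are retained; overlapping features are all kept.
#'
#' @param path Path to a GFF3 file.
#' @param types Character vector of feature types to keep (default `"CDS"`).
#' @return A data.frame of gene models with columns `gene_id`, `name`,
#'   `contig`, `start`, `end`, `strand`, `is_cds`, `phase`.
#' @export
read_gff <- function(path, types = "CDS") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[as.character(gr$type) %in% types]
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  pick <- function(cols) {
    out <- rep(NA_character_, length(gr))
    for (cl in cols) {
      if (cl %in% names(mc)) {
        v <- as.character(mc[[cl]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  gene_id <- pick(c("ID", "locus_tag", "Name", "gene"))
  gene_id[is.na(gene_id)] <- paste0("feature_", which(is.na(gene_id)))
  name <- pick(c("Name", "gene", "ID"))
  phase <- if ("phase" %in% names(mc)) {
    suppressWarnings(as.integer(as.character(mc$phase)))
  } else rep(0L, length(gr))
  phase[is.na(phase)] <- 0L
  genes <- data.frame(
    gene_id = gene_id,
    name = ifelse(is.na(name), gene_id, name),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_cds = as.character(gr$type) == "CDS",
    phase = phase,
    stringsAsFactors = FALSE
  )
  if (any(genes$end < genes$start)) stop("GFF3 feature with end < start")
  if (any(!genes$strand %in% c("+", "-"))) {
    # '*' strand features cannot be translated; keep but mark as plus
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  }
  genes
}

validate_genes <- function(genes, genome = NULL) {
  need <- c("gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(genes$phase)) genes$phase <- 0L
  if (is.null(genes$is_cds)) genes$is_cds <- TRUE
  stopifnot(all(genes$start >= 1L), all(genes$start <= genes$end))
  if (!is.null(genome)) {
    bad <- !genes$contig %in% names(genome$seq) |
      genes$end > genome$length[genes$contig]
    if (any(bad)) stop("gene(s) outside loaded contigs: ",
                       paste(genes$gene_id[bad], collapse = ", "))
  }
  genes
}

#' Write a reference genome and its gene models to FASTA + GFF3
#'
#' @param reference List with elements `genome` (a `reference_genome`) and
#'   `genes` (gene-model data.frame), as returned by [make_reference()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, gff_path) {
  dss <- Biostrings::DNAStringSet(reference$genome$seq)
  Biostrings::writeXStringSet(dss, fasta_path)
  g <- reference$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  gr$source <- "mutaccum"
  gr$type <- ifelse(g$is_cds, "CDS", "gene")
  gr$ID <- g$gene_id
  gr$Name <- g$name
  gr$phase <- as.integer(g$phase)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}
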