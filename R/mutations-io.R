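# Canonical column order for mutation-record tables. Annotation columns are
# optional until classify_mutations() has run.
REC_COLS <- c("sample", "contig", "pos", "ref", "alt", "mclass",
              "allele_frequency", "region", "effect", "spectrum_class",
              "gene_id", "ref_mismatch")

MCLASSES <- c("BPS", "insertion", "deletion")

#' Build a mutation-record table
#'
#' One row per called mutation. `mclass` is inferred from the allele lengths
#' when not supplied: equal single-base alleles are base-pair substitutions
#' (BPS); a longer alt is an insertion; a longer ref a deletion (VCF-style
#' anchored indels; the anchor base is excluded from indel length).
#'
#' @param sample,contig Character vectors (recycled).
#' @param pos 1-based positions.
#' @param ref,alt Alleles (A/C/G/T/N).
#' @param mclass Optional class, one of `"BPS"`, `"insertion"`, `"deletion"`.
#' @param allele_frequency Optional mutant allele frequency in (0, 1];
#'   `NA` for clonal (MA) records.
#' @return A validated data.frame of mutation records.
#' @export
mutation_records <- function(sample, contig, pos, ref, alt, mclass = NULL,
                             allele_frequency = NA_real_) {
  n <- max(length(sample), length(contig), length(pos), length(ref),
           length(alt))
  rec <- data.frame(
    sample = rep_len(as.character(sample), n),
    contig = rep_len(as.character(contig), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    stringsAsFactors = FALSE
  )
  if (is.null(mclass)) {
    rec$mclass <- ifelse(
      nchar(rec$ref) == 1L & nchar(rec$alt) == 1L, "BPS",
      ifelse(nchar(rec$alt) > nchar(rec$ref), "insertion", "deletion"))
  } else {
    rec$mclass <- rep_len(as.character(mclass), n)
  }
  rec$allele_frequency <- rep_len(as.numeric(allele_frequency), n)
  rec$region <- rep_len(NA_character_, n)
  rec$effect <- rep_len(NA_character_, n)
  rec$spectrum_class <- rep_len(NA_character_, n)
  rec$gene_id <- rep_len(NA_character_, n)
  rec$ref_mismatch <- rep_len(FALSE, n)
  validate_mutation_records(rec)
}

validate_mutation_records <- function(rec) {
  miss <- setdiff(c("sample", "contig", "pos", "ref", "alt", "mclass"),
                  names(rec))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(rec) == 0L) return(rec)
  if (any(grepl("[^ACGTN]", rec$ref)) || any(grepl("[^ACGTN]", rec$alt)))
    stop("ref/alt alleles must use the A/C/G/T/N alphabet")
  if (any(!rec$mclass %in% MCLASSES))
    stop("mclass must be one of: ", paste(MCLASSES, collapse = ", "))
  bps <- rec$mclass == "BPS"
  if (any(bps & (nchar(rec$ref) != 1L | nchar(rec$alt) != 1L)))
    stop("BPS records must have single-base ref and alt")
  if (any(bps & rec$ref == rec$alt))
    stop("BPS records must have ref != alt")
  ind <- !bps
  if (any(ind & abs(nchar(rec$ref) - nchar(rec$alt)) < 1L))
    stop("indel records must change allele length by >= 1")
  af <- rec$allele_frequency
  if (any(!is.na(af) & (af <= 0 | af > 1)))
    stop("allele_frequency must lie in (0, 1]")
  rec
}

#' Read mutation calls from VCF or TSV
#'
#' VCF positions are used as-is (1-based, never shifted). Multi-allelic VCF
#' rows are split into one record per alternate allele; an `AF` INFO field,
#' when present, is parsed into `allele_frequency` (comma-split in step with
#' the alternate alleles).
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"tsv"` (the package's own tab-separated layout,
#'   as written by [write_table()]).
#' @param sample_id Sample label for VCF input; defaults to the first
#'   genotype column name, or the file base name for site-only VCFs.
#' @return A mutation-record data.frame (see [mutation_records()]).
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (dialect == "tsv") {
    rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    if (nrow(rec) == 0L) {
      rec <- empty_records()
    } else {
      for (cl in setdiff(REC_COLS, names(rec))) {
        rec[[cl]] <- if (cl == "allele_frequency") NA_real_
                     else if (cl == "ref_mismatch") FALSE else NA_character_
      }
      rec <- rec[REC_COLS]
      rec$sample <- as.character(rec$sample)
      rec$contig <- as.character(rec$contig)
      rec$pos <- as.integer(rec$pos)
      rec$ref <- toupper(as.character(rec$ref))
      rec$alt <- toupper(as.character(rec$alt))
      rec$mclass <- as.character(rec$mclass)
      rec$allele_frequency <- as.numeric(rec$allele_frequency)
      for (cl in c("region", "effect", "spectrum_class", "gene_id"))
        rec[[cl]] <- as.character(rec[[cl]])
      rec$ref_mismatch <- as.logical(rec$ref_mismatch) %in% TRUE
    }
    return(validate_mutation_records(rec))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(sample_id)) {
    gt_samples <- colnames(v@gt)
    sample_id <- if (!is.null(gt_samples) && length(gt_samples) > 1L)
      gt_samples[2L] else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  af_raw <- suppressWarnings(vcfR::extract.info(v, element = "AF"))
  af_list <- if (is.null(af_raw)) {
    rep(list(NA_real_), nrow(fix))
  } else {
    lapply(strsplit(as.character(af_raw), ",", fixed = TRUE),
           function(x) suppressWarnings(as.numeric(x)))
  }
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  af <- unlist(mapply(function(a, f) rep_len(f, length(a)),
                      alt_list, af_list, SIMPLIFY = FALSE))
  mutation_records(
    sample = sample_id,
    contig = as.character(fix[idx, "CHROM"]),
    pos = as.integer(fix[idx, "POS"]),
    ref = as.character(fix[idx, "REF"]),
    alt = unlist(alt_list),
    allele_frequency = af
  )
}

empty_records <- function() {
  rec <- data.frame(sample = character(), contig = character(),
                    pos = integer(), ref = character(), alt = character(),
                    mclass = character(), allele_frequency = numeric(),
                    region = character(), effect = character(),
                    spectrum_class = character(), gene_id = character(),
                    ref_mismatch = logical(), stringsAsFactors = FALSE)
  rec
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row and a stable column order (mutation-record
#' columns first when present). Mutation tables round-trip through
#' [read_mutations()] with `dialect = "tsv"`.
#'
#' @param x A data.frame (mutation records, rate estimates, scan results, ...).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  known <- intersect(REC_COLS, names(x))
  if (length(known)) x <- x[c(known, setdiff(names(x), known))]
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to: ", path)
  invisible(path)
}
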