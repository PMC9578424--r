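#' Default six-class mutation spectrum
#'
#' Class probabilities of the untreated MA lines of the E. coli study the
#' package is built around (19, 35, 13, 18, 5, 15 events out of 105).
#'
#' @return Named numeric probabilities over [SPECTRUM_CLASSES], summing to 1.
#' @export
default_spectrum <- function() {
  setNames(c(19, 35, 13, 18, 5, 15) / 105, SPECTRUM_CLASSES)
}

#' Simulate a reference genome with non-overlapping CDS genes
#'
#' Random sequence at a target GC fraction, with `n_genes` single-exon CDS
#' genes (lengths forced to multiples of 3) placed without overlap on
#' random strands and separated by random intergenic gaps. Defaults mirror
#' an E. coli-like chromosome (GC 0.508, ~85% coding, 900-bp genes) at
#' whatever `length` the caller asks for.
#'
#' @param length Genome length in bp.
#' @param n_genes Number of genes; default fills `gene_fraction` of the
#'   genome.
#' @param gene_length CDS length in bp (rounded down to a multiple of 3).
#' @param gene_fraction Coding fraction used when `n_genes` is `NULL`.
#' @param gc GC content of the random sequence.
#' @param contig Contig name.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `genome` (a `reference_genome`) and `genes`
#'   (gene-model data.frame).
#' @export
make_reference <- function(length = 100000L, n_genes = NULL,
                           gene_length = 900L, gene_fraction = 0.85,
                           gc = 0.508, contig = "sim_1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  gene_length <- (as.integer(gene_length) %/% 3L) * 3L
  if (gene_length < 3L) stop("gene_length must be at least 3")
  if (is.null(n_genes)) n_genes <- floor(length * gene_fraction / gene_length)
  n_genes <- as.integer(n_genes)
  if (n_genes * gene_length > length)
    stop("gene demands exceed genome length")
  seq_chars <- sample(BASES, length, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome <- new_reference_genome(
    setNames(paste(seq_chars, collapse = ""), contig))
  if (n_genes > 0L) {
    slack <- length - n_genes * gene_length
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n_genes + 1L)))
    starts <- cumsum(c(1L, rep(gene_length, n_genes - 1L))) +
      cumsum(gaps[seq_len(n_genes)])
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      name = sprintf("g%04d", seq_len(n_genes)),
      contig = contig,
      start = starts,
      end = starts + gene_length - 1L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      is_cds = TRUE,
      phase = 0L,
      stringsAsFactors = FALSE
    )
  } else {
    genes <- data.frame(gene_id = character(), name = character(),
                        contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        is_cds = logical(), phase = integer(),
                        stringsAsFactors = FALSE)
  }
  list(genome = genome, genes = genes)
}

# draw alternate alleles from a six-class spectrum, conditional on ref base
draw_alt <- function(ref, spectrum) {
  vapply(ref, function(b) {
    alts <- setdiff(BASES, b)
    w <- spectrum[spectrum_class_of(rep(b, 3), alts)]
    sample(alts, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

# map linear 1..total positions to (contig, pos) for a multi-contig genome
linear_to_contig <- function(genome, lin) {
  ends <- cumsum(genome$length)
  ci <- findInterval(lin, ends, left.open = TRUE) + 1L
  offset <- c(0, ends[-length(ends)])
  data.frame(contig = names(genome$length)[ci],
             pos = as.integer(lin - offset[ci]),
             stringsAsFactors = FALSE)
}

#' Simulate a mutation-accumulation experiment
#'
#' Neutral accumulation under repeated single-colony bottlenecks: per line,
#' the mutation count is Poisson with mean `rate * N * T`; each event draws
#' its class from the configured six-class spectrum and its position
#' uniformly among the sites of that class's origin pair (A/T or G/C), so
#' realized class proportions converge on the configured ones. Mutations are
#' clonal singletons (no within-line polymorphism), matching single-colony
#' sequencing. Defaults reproduce the study design: 142 lines, 27.48 cell
#' divisions per daily transfer, 40 transfers, BPS rate 1.45e-10 and indel
#' rate 1.94e-11 per site per division.
#'
#' @param genome A `reference_genome`.
#' @param genes Gene models (unused by the neutral generator; accepted so
#'   simulator and analyses share one calling convention).
#' @param n_lines Number of MA lines.
#' @param bps_rate,indel_rate Per-site per-division rates.
#' @param divisions_per_transfer,transfers Transfer regime; `T` is their
#'   product.
#' @param spectrum Six-class probabilities (see [default_spectrum()]).
#' @param group Group label stored in the metadata.
#' @param seed Optional RNG seed.
#' @return List with `records` (mutation-record data.frame) and `metadata`
#'   (per-line `sample`, `T`, `N`, `group`).
#' @export
simulate_ma <- function(genome, genes = NULL, n_lines = 142L,
                        bps_rate = 1.45e-10, indel_rate = 1.94e-11,
                        divisions_per_transfer = 27.48, transfers = 40L,
                        spectrum = default_spectrum(), group = "control",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bps_rate < 0 || indel_rate < 0) stop("rates must be non-negative")
  if (abs(sum(spectrum) - 1) > 1e-6) stop("spectrum must sum to 1")
  n_sites <- sum(genome$length)
  T_div <- divisions_per_transfer * transfers
  if (T_div <= 0 || n_lines < 1L) stop("invalid MA design")
  if (bps_rate * T_div > 0.1)
    stop("expected mutation load exceeds 10% of sites per line; ",
         "the no-multi-hit MA approximation breaks down")
  # linear indices of A/T and G/C sites, so that drawing the spectrum class
  # first and then a position within its origin pair reproduces the
  # configured class probabilities exactly (and skips N sites)
  chars <- strsplit(paste(genome$seq, collapse = ""), "")[[1]]
  at_idx <- which(chars %in% c("A", "T"))
  gc_idx <- which(chars %in% c("G", "C"))
  at_class <- startsWith(SPECTRUM_CLASSES, "A:T")
  if ((length(at_idx) == 0L && sum(spectrum[at_class]) > 0) ||
      (length(gc_idx) == 0L && sum(spectrum[!at_class]) > 0))
    stop("genome lacks sites for a spectrum class with positive probability")

  recs <- list()
  samples <- sprintf("%s_MA%03d", group, seq_len(n_lines))
  for (i in seq_len(n_lines)) {
    m <- stats::rpois(1, bps_rate * n_sites * T_div)
    if (m > 0) {
      cls <- sample(SPECTRUM_CLASSES, m, replace = TRUE, prob = spectrum)
      is_at <- startsWith(cls, "A:T")
      lin <- integer(m)
      if (any(is_at))
        lin[is_at] <- at_idx[sample.int(length(at_idx), sum(is_at),
                                        replace = TRUE)]
      if (any(!is_at))
        lin[!is_at] <- gc_idx[sample.int(length(gc_idx), sum(!is_at),
                                         replace = TRUE)]
      ref <- chars[lin]
      # class "X:x>W:w": a site matching X mutates to W, its complement to w
      alt <- ifelse(ref == substr(cls, 1, 1), substr(cls, 5, 5),
                    substr(cls, 7, 7))
      loc <- linear_to_contig(genome, lin)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = samples[i], contig = loc$contig, pos = loc$pos,
        ref = ref, alt = alt, mclass = "BPS", stringsAsFactors = FALSE)
    }
    k <- stats::rpois(1, indel_rate * n_sites * T_div)
    if (k > 0) {
      loc <- linear_to_contig(genome,
                              sample.int(n_sites - 1L, k, replace = TRUE))
      anchor <- mapply(genome_base_at, contig = loc$contig, pos = loc$pos,
                       MoreArgs = list(genome = genome))
      nxt <- mapply(genome_base_at, contig = loc$contig, pos = loc$pos + 1L,
                    MoreArgs = list(genome = genome))
      ok <- anchor %in% BASES & nxt %in% BASES  # skip Ns and contig ends
      if (any(ok)) {
        ins <- sample(c(TRUE, FALSE), sum(ok), replace = TRUE)
        ref <- ifelse(ins, anchor[ok], paste0(anchor[ok], nxt[ok]))
        alt <- ifelse(ins, paste0(anchor[ok],
                                  sample(BASES, sum(ok), replace = TRUE)),
                      anchor[ok])
        recs[[length(recs) + 1L]] <- data.frame(
          sample = samples[i], contig = loc$contig[ok], pos = loc$pos[ok],
          ref = ref, alt = alt,
          mclass = ifelse(ins, "insertion", "deletion"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs)) {
    records <- do.call(rbind, recs)
    records$allele_frequency <- NA_real_
    records$region <- NA_character_
    records$effect <- NA_character_
    records$spectrum_class <- NA_character_
    records$gene_id <- NA_character_
    records$ref_mismatch <- FALSE
    records <- records[order(records$sample, records$contig, records$pos), ]
    rownames(records) <- NULL
  } else {
    records <- empty_records()
  }
  metadata <- data.frame(sample = samples, T = T_div, N = n_sites,
                         group = group, stringsAsFactors = FALSE)
  list(records = validate_mutation_records(records), metadata = metadata)
}

#' Simulate serial-transfer experimental evolution (Wright-Fisher)
#'
#' Discrete-cycle model of daily 1:1000 serial transfer: deterministic
#' exponential regrowth for `generations_per_cycle` doublings (haploid
#' selection multiplies a mutant's per-generation growth by `1 + s`),
#' followed by binomial sampling of every segregating site at the
#' bottleneck (the site-wise marginal of multinomial resampling under an
#' unlinked-sites approximation; drift at the 1000-fold dilution is the
#' dominant noise source). New neutral mutations enter during regrowth at
#' `mu` per site per cell division with an arising time weighted by the
#' number of divisions per generation; designated resistance loci receive
#' their own mutational supply (`locus_mutation_rate` expected new mutant
#' cells per cycle at the scaled population size).
#'
#' Populations are simulated at a scaled size (default 1e5 cells at full
#' growth) rather than census scale; selection coefficients are interpreted
#' at that scale.
#'
#' @param genome A `reference_genome`.
#' @param genes Gene models (positions only; may be `NULL`).
#' @param n_populations Parallel populations.
#' @param pop_size Approximate full-grown population size (scaled).
#' @param bottleneck_fraction Transfer dilution (default 1e-3).
#' @param generations_per_cycle Doublings per culturing cycle (default 10).
#' @param transfers Number of cycles (default 40).
#' @param mu Neutral per-site per-division mutation rate.
#' @param selected_loci Optional data.frame `contig`, `pos`, `s` of
#'   resistance loci under positive selection.
#' @param locus_mutation_rate Expected new mutant cells per selected locus
#'   per cycle (scaled mutational target size of the resistance loci).
#' @param detection_threshold Allele-frequency detection limit applied to
#'   the output (default 0.05, matching polymorphism-caller filtering).
#' @param spectrum Six-class spectrum for alternate-allele draws.
#' @param group Group label.
#' @param seed Optional RNG seed.
#' @return List with `records` (population mutation records carrying
#'   `allele_frequency`) and `metadata` (`sample`, `group`, `T`).
#' @export
simulate_evolution <- function(genome, genes = NULL, n_populations = 12L,
                               pop_size = 1e5, bottleneck_fraction = 1e-3,
                               generations_per_cycle = 10L, transfers = 40L,
                               mu = 1e-7, selected_loci = NULL,
                               locus_mutation_rate = 0.2,
                               detection_threshold = 0.05,
                               spectrum = default_spectrum(),
                               group = "treatment", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bottleneck_fraction <= 0 || bottleneck_fraction >= 1)
    stop("bottleneck_fraction must lie in (0, 1)")
  g <- as.integer(generations_per_cycle)
  n_b <- max(1L, round(pop_size * bottleneck_fraction))
  n_full <- n_b * 2^g
  if (n_full > 1e7) stop("scaled population too large for desk-scale runs")
  n_sites <- sum(genome$length)
  div_per_cycle <- n_full - n_b
  sel <- if (is.null(selected_loci)) {
    data.frame(contig = character(), pos = integer(), s = numeric(),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("contig", "pos", "s") %in% names(selected_loci)))
    if (any(selected_loci$s < -1)) stop("selection coefficients must be >= -1")
    selected_loci
  }
  arise_prob <- 2^(seq_len(g) - 1)  # divisions per generation grow 2x

  all_recs <- list()
  for (p in seq_len(n_populations)) {
    pop_name <- sprintf("%s_evo%02d", group, p)
    neut <- data.frame(lin = integer(), count = integer(), alt = character(),
                       stringsAsFactors = FALSE)
    sel_count <- rep(0L, nrow(sel))
    sel_alt <- rep(NA_character_, nrow(sel))
    p_end_neut <- numeric(0)
    p_end_sel <- numeric(0)
    for (cyc in seq_len(transfers)) {
      # regrowth of standing variants (haploid selection, deterministic)
      p_b <- neut$count / n_b
      p_end_neut <- p_b
      if (nrow(sel)) {
        pb_s <- sel_count / n_b
        wfac <- (1 + sel$s)^g
        p_end_sel <- pb_s * wfac / (pb_s * wfac + (1 - pb_s))
      }
      # new neutral mutations during regrowth
      n_new <- stats::rpois(1, mu * n_sites * div_per_cycle)
      if (n_new > 0) {
        t_arise <- sample.int(g, n_new, replace = TRUE, prob = arise_prob)
        p_new <- 2^(g - t_arise) / n_full
        lin_new <- sample.int(n_sites, n_new, replace = TRUE)
      } else {
        p_new <- numeric(0); lin_new <- integer(0)
      }
      # bottleneck: binomial sampling of every lineage
      keep_count <- stats::rbinom(length(p_end_neut), n_b, p_end_neut)
      new_count <- stats::rbinom(length(p_new), n_b, pmin(1, p_new))
      survivors <- keep_count > 0L
  newcomers <- new_count > 0L
      if (any(newcomers)) {
        ref_new <- mapply(genome_base_at,
                          contig = linear_to_contig(genome,
                                                    lin_new[newcomers])$contig,
                          pos = linear_to_contig(genome,
                                                 lin_new[newcomers])$pos,
                          MoreArgs = list(genome = genome))
        okn <- ref_new != "N"
        add <- data.frame(lin = lin_new[newcomers][okn],
                          count = new_count[newcomers][okn],
                          alt = draw_alt(ref_new[okn], spectrum),
                          stringsAsFactors = FALSE)
      } else add <- NULL
      neut <- rbind(data.frame(lin = neut$lin[survivors],
                               count = keep_count[survivors],
                               alt = neut$alt[survivors],
                               stringsAsFactors = FALSE), add)
      # collapse recurrent hits at the same site
      if (nrow(neut) > 1L && anyDuplicated(neut$lin)) {
        agg <- stats::aggregate(count ~ lin, data = neut, FUN = sum)
        agg$alt <- neut$alt[match(agg$lin, neut$lin)]
        neut <- agg[, c("lin", "count", "alt")]
      }
      neut$count <- pmin(neut$count, n_b)
      if (nrow(sel)) {
        sel_count <- stats::rbinom(nrow(sel), n_b, p_end_sel) +
          stats::rpois(nrow(sel), locus_mutation_rate)
        sel_count <- pmin(sel_count, n_b)
        need_alt <- sel_count > 0L & is.na(sel_alt)
        if (any(need_alt)) {
          ref_s <- mapply(genome_base_at, contig = sel$contig[need_alt],
                          pos = sel$pos[need_alt],
                          MoreArgs = list(genome = genome))
          sel_alt[need_alt] <- draw_alt(ref_s, spectrum)
        }
      }
    }
    # frequencies after the final regrowth
    p_fin_neut <- neut$count / n_b
    out <- NULL
    if (nrow(neut)) {
      loc <- linear_to_contig(genome, neut$lin)
      ref <- mapply(genome_base_at, contig = loc$contig, pos = loc$pos,
                    MoreArgs = list(genome = genome))
      out <- data.frame(sample = pop_name, contig = loc$contig,
                        pos = loc$pos, ref = unname(ref), alt = neut$alt,
                        mclass = "BPS", allele_frequency = p_fin_neut,
                        stringsAsFactors = FALSE)
    }
    if (nrow(sel)) {
      pb_s <- sel_count / n_b
      wfac <- (1 + sel$s)^g
      p_fin_sel <- pb_s * wfac / (pb_s * wfac + (1 - pb_s))
      keep <- p_fin_sel > 0
      if (any(keep)) {
        ref_s <- mapply(genome_base_at, contig = sel$contig[keep],
                        pos = sel$pos[keep],
                        MoreArgs = list(genome = genome))
        out <- rbind(out, data.frame(
          sample = pop_name, contig = sel$contig[keep], pos = sel$pos[keep],
          ref = unname(ref_s), alt = sel_alt[keep], mclass = "BPS",
          allele_frequency = p_fin_sel[keep], stringsAsFactors = FALSE))
      }
    }
    if (!is.null(out)) {
      out <- out[out$allele_frequency > detection_threshold, , drop = FALSE]
      if (nrow(out)) all_recs[[length(all_recs) + 1L]] <- out
    }
  }
  if (length(all_recs)) {
    records <- do.call(rbind, all_recs)
    records$region <- NA_character_
    records$effect <- NA_character_
    records$spectrum_class <- NA_character_
    records$gene_id <- NA_character_
    records$ref_mismatch <- FALSE
    rownames(records) <- NULL
  } else {
    records <- empty_records()
  }
  metadata <- data.frame(sample = sprintf("%s_evo%02d", group,
                                          seq_len(n_populations)),
                         group = group,
                         T = transfers * g,
                         stringsAsFactors = FALSE)
  list(records = validate_mutation_records(records), metadata = metadata)
}

#' Pure Wright-Fisher drift of one biallelic site
#'
#' Binomial resampling of a single allele frequency for `generations`
#' generations at constant size `N`, with no mutation or selection. Exposed
#' for calibrating the drift behavior of the serial-transfer simulator
#' against the classical variance formula
#' `p(1-p) * (1 - (1 - 1/N)^t)`.
#'
#' @param p0 Starting allele frequency.
#' @param N Population size.
#' @param generations Number of generations.
#' @param reps Number of independent replicate trajectories.
#' @return Numeric vector (`reps` long) of final allele frequencies.
#' @export
simulate_drift <- function(p0, N, generations, reps = 1L) {
  stopifnot(p0 >= 0, p0 <= 1, N >= 1, generations >= 0)
  counts <- rep(round(p0 * N), reps)
  for (t in seq_len(generations)) {
    counts <- stats::rbinom(reps, N, counts / N)
  }
  counts / N
}

#' Simulate a CFU plating series
#'
#' Replicate colony counts are Poisson with mean `true_eop * reference_cfu`
#' at each concentration; the no-drug control plates are Poisson at
#' `reference_cfu`.
#'
#' @param true_eop Named numeric vector of true plating efficiencies in
#'   `[0, 1]`, named by concentration.
#' @param reference_cfu Expected CFU on the untreated plate.
#' @param replicates Replicate plates per concentration.
#' @param seed Optional RNG seed.
#' @return Data.frame `concentration`, `replicate`, `cfu`, `reference_cfu`.
#' @export
simulate_plating <- function(true_eop, reference_cfu, replicates = 3L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(true_eop))) stop("true_eop must be named by concentration")
  if (any(true_eop < 0 | true_eop > 1)) stop("true_eop must lie in [0, 1]")
  if (reference_cfu <= 0 || replicates < 1) stop("invalid plating design")
  conc <- as.numeric(names(true_eop))
  ref_counts <- stats::rpois(replicates, reference_cfu)
  do.call(rbind, lapply(seq_along(conc), function(i) {
    data.frame(concentration = conc[i],
               replicate = seq_len(replicates),
               cfu = stats::rpois(replicates, true_eop[i] * reference_cfu),
               reference_cfu = ref_counts,
               stringsAsFactors = FALSE)
  }))
}
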