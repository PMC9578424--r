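#' Gene-level mutation hotspot test
#'
#' Under mutation-rate homogeneity each gene expects
#' `M * length / total_sites` hits, where `M` is the total number of
#' mutations observed. The upper-tail Poisson probability of each gene's
#' observed hit count is Bonferroni-corrected; mutations inside several
#' overlapping genes count toward every one of them.
#'
#' @param records Mutation-record data.frame (positions are re-intersected
#'   with `genes`, so prior annotation is not required).
#' @param genes Gene-model data.frame.
#' @param total_sites Total analyzed sites (bp).
#' @param alpha Family-wise significance level.
#' @param family Bonferroni family: `"all"` genes in the annotation
#'   (default, conservative and deterministic) or only `"tested"` genes with
#'   at least one hit.
#' @return Data.frame sorted by adjusted p-value: `gene_id`, `length_bp`,
#'   `observed`, `expected`, `p_raw`, `p_adj`, `significant`.
#' @export
gene_hit_test <- function(records, genes, total_sites, alpha = 0.05,
                          family = c("all", "tested")) {
  family <- match.arg(family)
  genes <- validate_genes(genes)
  if (total_sites <= 0) stop("total_sites must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  hit_idx <- overlap_gene_index(records, genes)
  observed <- tabulate(unlist(hit_idx), nbins = nrow(genes))
  len <- genes$end - genes$start + 1L
  m_total <- nrow(records)
  expected <- m_total * len / total_sites
  p_raw <- stats::ppois(observed - 1, expected, lower.tail = FALSE)
  n_fam <- if (family == "all") nrow(genes) else max(1L, sum(observed > 0))
  out <- data.frame(gene_id = genes$gene_id, length_bp = len,
                    observed = observed, expected = expected,
                    p_raw = p_raw, p_adj = pmin(1, p_raw * n_fam),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  attr(out, "family_size") <- n_fam
  out[order(out$p_adj, out$p_raw, out$gene_id), ]
}

#' Filter population variants by allele frequency
#'
#' Strictly-greater-than filter (a call at exactly the threshold is
#' dropped), preserving record order. Idempotent.
#'
#' @param records Population mutation records with `allele_frequency` set.
#' @param min_freq Detection threshold (default 0.05, i.e. keep > 5%).
#' @return The retained records.
#' @export
filter_population_variants <- function(records, min_freq = 0.05) {
  if (nrow(records) == 0L) return(records)
  if (any(is.na(records$allele_frequency)))
    stop(sum(is.na(records$allele_frequency)),
         " record(s) missing allele_frequency")
  records[records$allele_frequency > min_freq, , drop = FALSE]
}

#' Mean mutant allele frequency per gene and group
#'
#' Averages the retained site frequencies of each gene across all
#' populations of a group; sites with no retained variant contribute
#' nothing (frequency-zero sites are unobservable in polymorphism-caller
#' output). Intergenic sites are assigned to a pseudo-gene labeled by the
#' nearest annotated gene (`intergenic:<gene>`).
#'
#' @param records Filtered population records (see
#'   [filter_population_variants()]).
#' @param genes Gene-model data.frame.
#' @param metadata Data.frame mapping `sample` to `group`.
#' @return Data.frame `gene_id` x `group` with `mean_freq` and `n_sites`,
#'   sorted by decreasing mean frequency.
#' @export
mean_allele_frequency_by_gene <- function(records, genes, metadata) {
  stopifnot(all(c("sample", "group") %in% names(metadata)))
  if (nrow(records) == 0L)
    return(data.frame(gene_id = character(), group = character(),
                      mean_freq = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  if (any(is.na(records$allele_frequency)))
    stop("records must carry allele frequencies")
  genes <- validate_genes(genes)
  hit_idx <- overlap_gene_index(records, genes)
  labels <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    if (length(hit_idx[[i]])) {
      labels[[i]] <- genes$gene_id[hit_idx[[i]]]
    } else {
      labels[[i]] <- paste0("intergenic:",
                            nearest_gene_label(records$contig[i],
                                               records$pos[i], genes))
    }
  }
  grp <- metadata$group[match(records$sample, metadata$sample)]
  if (any(is.na(grp))) stop("record sample(s) missing from metadata")
  expand <- data.frame(
    gene_id = unlist(labels),
    group = rep(grp, lengths(labels)),
    freq = rep(records$allele_frequency, lengths(labels)),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(freq ~ gene_id + group, data = expand,
                          FUN = mean)
  names(agg)[names(agg) == "freq"] <- "mean_freq"
  agg$n_sites <- stats::aggregate(freq ~ gene_id + group, data = expand,
                                  FUN = length)$freq
  agg[order(-agg$mean_freq, agg$gene_id), ]
}

nearest_gene_label <- function(contig, pos, genes) {
  on_ct <- genes[genes$contig == contig, , drop = FALSE]
  if (nrow(on_ct) == 0L) return(contig)
  d <- pmax(0L, pmax(on_ct$start - pos, pos - on_ct$end))
  on_ct$gene_id[which.min(d)]
}

#' Per-gene Ka/Ks from observed mutation events
#'
#' `Ka` is the nonsynonymous mutation count divided by the gene's
#' (fractional) nonsynonymous sites, `Ks` the synonymous analogue. Because
#' within-experiment counts are sparse, no multiple-hit (Jukes-Cantor)
#' correction is applied. Genes with zero synonymous mutations receive a
#' pseudo-`Ks` from [calibrate_ks()] and are flagged `calibrated`.
#'
#' @param records Annotated (and, in population mode, frequency-filtered)
#'   mutation records; only BPS rows with a synonymous/nonsynonymous effect
#'   are counted.
#' @param opportunities A `site_opportunities` object for the same
#'   annotation.
#' @return Data.frame: `gene_id`, `nonsyn_n`, `syn_n`, `nonsyn_sites`,
#'   `syn_sites`, `ka`, `ks`, `ka_ks`, `calibrated`.
#' @export
ka_ks <- function(records, opportunities) {
  per <- opportunities$per_gene
  cod <- records[records$mclass == "BPS" &
                   records$effect %in% c("synonymous", "nonsynonymous") &
                   !is.na(records$gene_id), , drop = FALSE]
  if (nrow(cod) == 0L)
    return(data.frame(gene_id = character(), nonsyn_n = integer(),
                      syn_n = integer(), nonsyn_sites = numeric(),
                      syn_sites = numeric(), ka = numeric(), ks = numeric(),
                      ka_ks = numeric(), calibrated = logical(),
                      stringsAsFactors = FALSE))
  # overlap records carry comma-joined gene ids: attribute to every gene
  gsplit <- strsplit(cod$gene_id, ",", fixed = TRUE)
  flat <- data.frame(gene_id = unlist(gsplit),
                     effect = rep(cod$effect, lengths(gsplit)),
                     stringsAsFactors = FALSE)
  ids <- sort(unique(flat$gene_id))
  miss <- setdiff(ids, per$gene_id)
  if (length(miss)) stop("gene(s) absent from site opportunities: ",
                         paste(miss, collapse = ", "))
  sites <- per[match(ids, per$gene_id), ]
  if (any(sites$syn_sites <= 0))
    stop("gene(s) with zero synonymous sites: ",
         paste(ids[sites$syn_sites <= 0], collapse = ", "))
  nonsyn_n <- vapply(ids, function(g)
    sum(flat$gene_id == g & flat$effect == "nonsynonymous"), integer(1))
  syn_n <- vapply(ids, function(g)
    sum(flat$gene_id == g & flat$effect == "synonymous"), integer(1))
  ka <- nonsyn_n / sites$nonsyn_sites
  ks <- syn_n / sites$syn_sites
  calibrated <- syn_n == 0L
  if (any(calibrated)) {
    calib <- data.frame(syn_sites = sites$syn_sites[!calibrated],
                        syn_count = syn_n[!calibrated])
    if (nrow(calib) >= 2L) {
      ks[calibrated] <- calibrate_ks(calib, sites$syn_sites[calibrated])
    } else {
      # too few genes with synonymous hits to fit the regression:
      # fall back to the bare half-count floor
      warning("fewer than 2 genes with synonymous mutations; ",
              "pseudo-Ks uses the 0.5-count floor without regression")
      ks[calibrated] <- 0.5 / sites$syn_sites[calibrated]
    }
  }
  data.frame(gene_id = ids, nonsyn_n = nonsyn_n, syn_n = syn_n,
             nonsyn_sites = sites$nonsyn_sites, syn_sites = sites$syn_sites,
             ka = ka, ks = ks, ka_ks = ka / ks, calibrated = calibrated,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pseudo-Ks calibration for genes without synonymous mutations
#'
#' Least-squares regression, forced through the origin, of synonymous
#' mutation count on synonymous site count across genes with at least one
#' synonymous mutation. The predicted count at the target gene's synonymous
#' sites, floored at half an event (0.5), divided by its synonymous sites
#' gives the pseudo-`Ks`.
#'
#' @param calibration Data.frame with columns `syn_sites` and `syn_count`
#'   (genes with `syn_count >= 1`); at least two rows required.
#' @param target_syn_sites Synonymous site counts of the gene(s) to
#'   calibrate (vectorized).
#' @param floor Minimum pseudo-count (default 0.5).
#' @return Numeric pseudo-`Ks` values.
#' @export
calibrate_ks <- function(calibration, target_syn_sites, floor = 0.5) {
  stopifnot(all(c("syn_sites", "syn_count") %in% names(calibration)))
  calibration <- calibration[calibration$syn_count >= 1, , drop = FALSE]
  if (nrow(calibration) < 2L)
    stop("need at least two calibration genes with >= 1 synonymous mutation")
  if (any(target_syn_sites <= 0)) stop("target syn sites must be positive")
  slope <- sum(calibration$syn_sites * calibration$syn_count) /
    sum(calibration$syn_sites^2)
  pseudo_count <- pmax(floor, slope * target_syn_sites)
  pseudo_count / target_syn_sites
}
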