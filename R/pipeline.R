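#' Executable fixture of the study's printed MA count table
#'
#' The published count table of the E. coli MA experiment as an executable
#' object: control lines (n = 142, ~1099 cell divisions each) accumulated
#' 105 base substitutions (54 transitions / 51 transversions; spectrum
#' 19, 35, 13, 18, 5, 15) plus 7 insertions and 7 deletions; treated lines
#' (n = 172, ~1112 divisions) accumulated 98 substitutions (57/41; spectrum
#' 23, 34, 14, 13, 2, 12) plus 7 insertions and 9 deletions. Analyzed sites
#' per line default to the full MG1655 genome length (4,641,652 bp).
#'
#' @return A list with elements `control` and `treatment`, each holding
#'   `spectrum` (a `spectrum_counts`), `metadata` (per-line data.frame),
#'   `n_lines`, `divisions`, `sites`, and `categories` (region/effect
#'   counts: intergenic, coding, overlap, synonymous, nonsynonymous).
#' @export
table2_fixture <- function() {
  sites <- 4641652L
  make_group <- function(group, n, T_div, classes, ins, del, categories) {
    list(
      spectrum = new_spectrum_counts(
        setNames(classes, SPECTRUM_CLASSES), ins, del),
      metadata = data.frame(
        sample = sprintf("%s_MA%03d", group, seq_len(n)),
        T = T_div, N = sites, group = group, stringsAsFactors = FALSE),
      n_lines = n, divisions = T_div, sites = sites,
      categories = categories)
  }
  list(
    control = make_group("control", 142L, 1099,
                         c(19L, 35L, 13L, 18L, 5L, 15L), 7L, 7L,
                         c(intergenic = 24L, coding = 81L, overlap = 1L,
                           synonymous = 17L, nonsynonymous = 63L)),
    treatment = make_group("treatment", 172L, 1112,
                           c(23L, 34L, 14L, 13L, 2L, 12L), 7L, 9L,
                           c(intergenic = 19L, coding = 79L, overlap = 0L,
                             synonymous = 20L, nonsynonymous = 59L))
  )
}

#' Run the full simulate-annotate-test pipeline
#'
#' End-to-end reproducible run: builds (or loads) a reference, simulates MA
#' lines for two groups and serial-transfer populations, annotates every
#' mutation, and writes `rates.tsv`, `spectrum.tsv`, `scan.tsv` and
#' `phenotype.tsv` plus a `run.log` recording the seed and every threshold.
#' Identical config + seed give byte-identical tables.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized fields (all optional, with desk-scale-capable
#'   defaults): `seed`, `outdir`, `reference` (`length`, `n_genes`,
#'   `gene_length`, `gc`), `ma` (per-group lists of [simulate_ma()]
#'   arguments under `control`/`treatment`), `evolution`
#'   ([simulate_evolution()] arguments), `plating` (`true_eop` named by
#'   concentration, `reference_cfu`, `replicates`), `thresholds`
#'   (`ci_level`, `min_freq`, `alpha`).
#' @return Invisibly, a list of the in-memory result tables and the output
#'   directory.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  set.seed(cfg$seed)
  log_lines <- c(sprintf("mutaccum %s",
                         as.character(utils::packageVersion("mutaccum"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("ci_level: %g", cfg$thresholds$ci_level),
                 sprintf("min_freq: %g", cfg$thresholds$min_freq),
                 sprintf("alpha: %g", cfg$thresholds$alpha))

  ref <- do.call(make_reference, cfg$reference)
  opp <- count_site_opportunities(ref$genome, ref$genes)
  log_lines <- c(log_lines,
                 sprintf("reference: %d bp, %d genes", sum(ref$genome$length),
                         nrow(ref$genes)))

  # --- MA stage: rates and spectra per group -------------------------------
  groups <- names(cfg$ma)
  ma <- lapply(groups, function(g) {
    args <- c(list(genome = ref$genome, genes = ref$genes, group = g),
              cfg$ma[[g]])
    sim <- do.call(simulate_ma, args)
    sim$records <- classify_mutations(sim$records, ref$genome, ref$genes)
    sim
  })
  names(ma) <- groups
  lvl <- cfg$thresholds$ci_level
  rates <- do.call(rbind, lapply(groups, function(g) {
    r1 <- estimate_rate(ma[[g]]$records, ma[[g]]$metadata, "BPS", lvl)
    r2 <- estimate_rate(ma[[g]]$records, ma[[g]]$metadata, "indel", lvl)
    ff <- tryCatch(fourfold_rate(ma[[g]]$records, opp, ma[[g]]$metadata, lvl),
                   error = function(e) NULL)
    out <- rbind(as.data.frame(r1), as.data.frame(r2),
                 if (!is.null(ff)) as.data.frame(ff))
    cbind(group = g, out)
  }))
  write_table(rates, file.path(cfg$outdir, "rates.tsv"))

  spec_tab <- do.call(rbind, lapply(groups, function(g) {
    cbind(group = g,
          as.data.frame(spectrum_counts(ma[[g]]$records)))
  }))
  write_table(spec_tab, file.path(cfg$outdir, "spectrum.tsv"))
  if (length(groups) == 2L) {
    s1 <- spectrum_counts(ma[[groups[1]]]$records)
    s2 <- spectrum_counts(ma[[groups[2]]]$records)
    tab <- rbind(c(transitions(s1), transversions(s1)),
                 c(transitions(s2), transversions(s2)))
    ts_test <- tryCatch(chi2_2x2(tab), error = function(e) NULL)
    if (!is.null(ts_test))
      log_lines <- c(log_lines,
                     sprintf("ts/tv 2x2 (%s vs %s): chi2 = %.4g, P = %.4g",
                             groups[1], groups[2], ts_test$statistic,
                             ts_test$p.value))
  }
  for (g in groups) {
    rec <- ma[[g]]$records
    ns <- sum(rec$effect %in% "nonsynonymous" & rec$region == "coding")
    sy <- sum(rec$effect %in% "synonymous" & rec$region == "coding")
    if (ns + sy > 0) {
      nt <- ns_s_neutrality_test(ns, sy, neutral_ns_ratio(opp))
      log_lines <- c(log_lines,
                     sprintf("neutrality %s: nonsyn %d syn %d chi2 = %.4g P = %.4g",
                             g, ns, sy, nt$statistic, nt$p.value))
    }
  }

  # --- selection stage: hotspots, allele frequencies, Ka/Ks ----------------
  evo_args <- c(list(genome = ref$genome, genes = ref$genes,
                     detection_threshold = cfg$thresholds$min_freq),
                cfg$evolution)
  evo <- do.call(simulate_evolution, evo_args)
  evo$records <- classify_mutations(evo$records, ref$genome, ref$genes)
  evo$records <- filter_population_variants(evo$records,
                                            cfg$thresholds$min_freq)
  hot <- gene_hit_test(ma[[groups[length(groups)]]]$records, ref$genes,
                       total_sites = sum(ref$genome$length),
                       alpha = cfg$thresholds$alpha)
  log_lines <- c(log_lines,
                 sprintf("hotspot Bonferroni family: %d genes",
                         attr(hot, "family_size")),
                 sprintf("hotspot significant genes: %d",
                         sum(hot$significant)))
  kk <- ka_ks(evo$records, opp)
  maf <- mean_allele_frequency_by_gene(evo$records, ref$genes, evo$metadata)
  scan <- merge(maf, kk, by = "gene_id", all.x = TRUE, sort = FALSE)
  scan <- scan[order(-scan$mean_freq, scan$gene_id), ]
  write_table(scan, file.path(cfg$outdir, "scan.tsv"))
  write_table(hot, file.path(cfg$outdir, "hotspots.tsv"))

  # --- phenotype stage -----------------------------------------------------
  plating <- simulate_plating(unlist(cfg$plating$true_eop),
                              cfg$plating$reference_cfu,
                              cfg$plating$replicates)
  mic <- tryCatch(mic_from_series(plating), error = function(e) NA_real_)
  pheno <- stats::aggregate(cfu ~ concentration, data = plating, FUN = mean)
  pheno$eop <- pheno$cfu / cfg$plating$reference_cfu
  pheno$mic <- mic
  write_table(pheno, file.path(cfg$outdir, "phenotype.tsv"))
  log_lines <- c(log_lines, sprintf("MIC: %s", format(mic)))

  writeLines(log_lines, file.path(cfg$outdir, "run.log"))
  invisible(list(rates = rates, spectrum = spec_tab, scan = scan,
                 hotspots = hot, phenotype = pheno, outdir = cfg$outdir))
}

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = file.path(tempdir(), "mutaccum_run"),
    reference = list(length = 50000L, n_genes = 40L, gene_length = 900L,
                     gc = 0.508),
    ma = list(
      control = list(n_lines = 40L, bps_rate = 2e-8, indel_rate = 2e-9,
                     divisions_per_transfer = 27.48, transfers = 40L),
      treatment = list(n_lines = 40L, bps_rate = 2e-8, indel_rate = 2e-9,
                       divisions_per_transfer = 27.81, transfers = 40L)
    ),
    evolution = list(n_populations = 6L, pop_size = 1e5,
                     bottleneck_fraction = 1e-3,
                     generations_per_cycle = 10L, transfers = 20L,
                     mu = 5e-7),
    plating = list(true_eop = list(`0` = 1, `20` = 0.4, `40` = 0.1,
                                   `60` = 0, `80` = 0),
                   reference_cfu = 1000, replicates = 3L),
    thresholds = list(ci_level = 0.95, min_freq = 0.05, alpha = 0.05)
  )
}
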