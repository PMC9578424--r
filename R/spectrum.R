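#' Tally the six-class base-substitution spectrum
#'
#' Partitions annotated records exhaustively into the six collapsed BPS
#' classes plus insertions and deletions.
#'
#' @param records Mutation-record data.frame with `spectrum_class` set for
#'   every BPS row (see [classify_mutations()]); unannotated BPS rows are an
#'   error, never silently dropped.
#' @return A `spectrum_counts` object.
#' @export
spectrum_counts <- function(records) {
  bps <- records[records$mclass == "BPS", , drop = FALSE]
  if (any(is.na(bps$spectrum_class)))
    stop(sum(is.na(bps$spectrum_class)),
         " BPS record(s) lack a spectrum_class; run classify_mutations()")
  classes <- table(factor(bps$spectrum_class, levels = SPECTRUM_CLASSES))
  new_spectrum_counts(setNames(as.integer(classes), SPECTRUM_CLASSES),
                      insertions = sum(records$mclass == "insertion"),
                      deletions = sum(records$mclass == "deletion"))
}

#' Construct spectrum counts directly
#'
#' For building executable fixtures from published count tables.
#'
#' @param classes Named integer vector over [SPECTRUM_CLASSES].
#' @param insertions,deletions Indel counts.
#' @return A `spectrum_counts` object.
#' @export
new_spectrum_counts <- function(classes, insertions = 0L, deletions = 0L) {
  if (!all(SPECTRUM_CLASSES %in% names(classes)))
    stop("classes must be named by the six spectrum classes")
  classes <- setNames(as.integer(classes[SPECTRUM_CLASSES]), SPECTRUM_CLASSES)
  if (any(classes < 0) || insertions < 0 || deletions < 0)
    stop("counts must be non-negative")
  structure(list(classes = classes,
                 insertions = as.integer(insertions),
                 deletions = as.integer(deletions)),
            class = "spectrum_counts")
}

#' @rdname spectrum_counts
#' @param x A `spectrum_counts` object.
#' @export
transitions <- function(x) sum(x$classes[TRANSITION_CLASSES])

#' @rdname spectrum_counts
#' @export
transversions <- function(x) sum(x$classes) - transitions(x)

#' @rdname spectrum_counts
#' @export
bps_total <- function(x) sum(x$classes)

#' @export
print.spectrum_counts <- function(x, ...) {
  cat("<spectrum_counts> BPS", bps_total(x),
      "(ts", transitions(x), "/ tv", transversions(x), ")",
      "ins", x$insertions, "del", x$deletions, "\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum_counts <- function(x, ...) {
  ts <- transitions(x); tv <- transversions(x); tot <- bps_total(x)
  data.frame(
    category = c("Transitions", TRANSITION_CLASSES, "Transversions",
                 setdiff(SPECTRUM_CLASSES, TRANSITION_CLASSES),
                 "Insertions", "Deletions"),
    count = c(ts, unname(x$classes[TRANSITION_CLASSES]), tv,
              unname(x$classes[setdiff(SPECTRUM_CLASSES,
                                       TRANSITION_CLASSES)]),
              x$insertions, x$deletions),
    proportion = c(
      if (tot > 0) ts / tot else NA,
      if (ts > 0) unname(x$classes[TRANSITION_CLASSES]) / ts else c(NA, NA),
      if (tot > 0) tv / tot else NA,
      if (tv > 0) unname(x$classes[setdiff(SPECTRUM_CLASSES,
                                           TRANSITION_CLASSES)]) / tv
      else rep(NA, 4),
      if (x$insertions + x$deletions > 0)
        c(x$insertions, x$deletions) / (x$insertions + x$deletions)
      else c(NA, NA)),
    stringsAsFactors = FALSE
  )
}

#' Transition-to-transversion ratio
#'
#' @param spectrum A `spectrum_counts` object.
#' @return `transitions / transversions`.
#' @export
ts_tv_ratio <- function(spectrum) {
  tv <- transversions(spectrum)
  if (tv == 0) stop("ts/tv ratio undefined: zero transversions")
  transitions(spectrum) / tv
}

#' Pearson chi-square test on a 2x2 table
#'
#' With `yates = TRUE` (the default), each `|O - E|` is shrunk by 0.5 and
#' floored at 0 before squaring (Yates continuity correction), the
#' construction that matches published small-table statistics exactly.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates Apply the continuity correction?
#' @return A `mut_test` list: `statistic`, `df`, `p.value`, `correction`.
#' @export
chi2_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("2x2 table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(statistic = unname(res$statistic), df = 1L,
                 p.value = res$p.value,
                 correction = if (yates) "yates" else "none"),
            class = "mut_test")
}

#' @export
print.mut_test <- function(x, ...) {
  cat(sprintf("chi^2 = %.4g, df = %d, P = %.3g (%s)\n",
              x$statistic, x$df, x$p.value, x$correction))
  invisible(x)
}

#' Neutrality test of the nonsynonymous-to-synonymous ratio
#'
#' One-degree-of-freedom goodness-of-fit of the observed (nonsynonymous,
#' synonymous) counts against the neutral expectation `r : 1`, where `r`
#' comes from the site opportunities (see [neutral_ns_ratio()]) and is
#' treated as a fixed, known quantity.
#'
#' @param observed_nonsyn,observed_syn Observed mutation counts.
#' @param expected_ratio Neutral nonsyn:syn ratio (> 0).
#' @return A `mut_test` list (uncorrected Pearson statistic, df = 1).
#' @export
ns_s_neutrality_test <- function(observed_nonsyn, observed_syn,
                                 expected_ratio) {
  if (expected_ratio <= 0) stop("expected_ratio must be positive")
  total <- observed_nonsyn + observed_syn
  if (total <= 0) stop("total observed count is zero")
  p <- c(expected_ratio, 1) / (expected_ratio + 1)
  res <- suppressWarnings(
    stats::chisq.test(c(observed_nonsyn, observed_syn), p = p))
  structure(list(statistic = unname(res$statistic), df = 1L,
                 p.value = res$p.value, correction = "none"),
            class = "mut_test")
}
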