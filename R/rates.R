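#' Exact Poisson confidence interval via chi-square quantiles
#'
#' Garwood's interval for a Poisson count `m` observed over `denominator`
#' units of exposure: `low = chisq_{alpha/2}(2m)/2/denominator` (0 when
#' `m = 0`) and `high = chisq_{1-alpha/2}(2m+2)/2/denominator`, with
#' `alpha = 1 - level`. This is the Poisson cumulative distribution function
#' inverted through its chi-square representation.
#'
#' @param m Non-negative integer event count.
#' @param denominator Positive exposure (e.g. summed site-divisions).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(low, high)` on the per-exposure-unit scale.
#' @export
poisson_ci <- function(m, denominator = 1, level = 0.95) {
  if (length(m) != 1L || is.na(m) || m < 0 || abs(m - round(m)) > 1e-8)
    stop("m must be a single non-negative integer")
  if (denominator <= 0) stop("denominator must be positive")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  m <- round(m)
  alpha <- 1 - level
  low <- if (m == 0) 0 else stats::qchisq(alpha / 2, 2 * m) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * m + 2) / 2
  c(low = low / denominator, high = high / denominator)
}

new_rate_estimate <- function(mclass, m, denominator, rate, sem,
                              ci, level) {
  structure(data.frame(mclass = mclass, m = m, denominator = denominator,
                       rate = rate, sem = sem,
                       ci_low = ci[["low"]], ci_high = ci[["high"]],
                       level = level, stringsAsFactors = FALSE),
            class = c("rate_estimate", "data.frame"))
}

#' Estimate a genome-wide mutation rate from MA data
#'
#' The mean per-site per-cell-division rate is `m / sum_i(N_i * T_i)`, where
#' `m` counts mutations of the requested class across all lines, and each
#' line contributes its analyzed sites `N_i` times its cell divisions `T_i`
#' to the denominator. The SEM is the sample standard deviation of the
#' per-line rates `m_i / (N_i * T_i)` divided by `sqrt(n)`; the confidence
#' interval is the exact chi-square (Garwood) Poisson interval.
#'
#' @param records Mutation-record data.frame.
#' @param metadata Per-line data.frame with columns `sample`, `T`, `N`
#'   (and optionally `group`).
#' @param mclass `"BPS"` (substitutions) or `"indel"`
#'   (insertions + deletions).
#' @param level Confidence level.
#' @return A one-row `rate_estimate` data.frame with columns `mclass`, `m`,
#'   `denominator`, `rate`, `sem`, `ci_low`, `ci_high`, `level`.
#' @export
estimate_rate <- function(records, metadata, mclass = c("BPS", "indel"),
                          level = 0.95) {
  mclass <- match.arg(mclass)
  if (is.null(metadata) || nrow(metadata) == 0L) stop("empty metadata")
  stopifnot(all(c("sample", "T", "N") %in% names(metadata)))
  if (any(metadata$T <= 0) || any(metadata$N <= 0))
    stop("metadata T and N must be positive")
  keep <- if (mclass == "BPS") records$mclass == "BPS"
          else records$mclass %in% c("insertion", "deletion")
  rec <- records[keep, , drop = FALSE]
  unknown <- setdiff(unique(rec$sample), metadata$sample)
  if (length(unknown)) stop("record sample(s) missing from metadata: ",
                            paste(unknown, collapse = ", "))
  denom_i <- metadata$N * metadata$T
  denominator <- sum(denom_i)
  if (denominator <= 0) stop("denominator is zero")
  m <- nrow(rec)
  m_i <- as.integer(table(factor(rec$sample, levels = metadata$sample)))
  r_i <- m_i / denom_i
  n <- nrow(metadata)
  sem <- if (n > 1) stats::sd(r_i) / sqrt(n) else NA_real_
  new_rate_estimate(mclass, m, denominator, m / denominator, sem,
                    poisson_ci(m, denominator, level), level)
}

#' Rate estimate from printed summary counts
#'
#' Convenience constructor for published designs where only the event total,
#' the number of lines, and per-line divisions/sites are known (no per-line
#' counts, hence no SEM).
#'
#' @param m Event count summed over lines.
#' @param n_lines Number of MA lines.
#' @param divisions Cell divisions per line (`T`).
#' @param sites Analyzed sites per line (`N`), defaulting to the E. coli
#'   K-12 MG1655 genome length.
#' @param level Confidence level.
#' @return A one-row `rate_estimate` data.frame.
#' @export
rate_from_counts <- function(m, n_lines, divisions, sites = 4641652,
                             level = 0.95) {
  denominator <- n_lines * sites * divisions
  new_rate_estimate("BPS", m, denominator, m / denominator, NA_real_,
                    poisson_ci(m, denominator, level), level)
}

#' Per-class conditional mutation rates
#'
#' Each of the six collapsed spectrum classes is scaled by the number of
#' sites at which it can originate: A:T-origin classes divide by the genome's
#' A/T site count, G:C-origin classes by its G/C count, each multiplied by
#' the summed cell divisions of the lines.
#'
#' @param spectrum A `spectrum_counts` object.
#' @param opportunities A `site_opportunities` object (for `at_sites` /
#'   `gc_sites`).
#' @param metadata Per-line metadata (for summed `T`).
#' @param level Confidence level.
#' @return Data.frame with one row per class: `class`, `m`, `origin_sites`,
#'   `denominator`, `rate`, `ci_low`, `ci_high`.
#' @export
conditional_spectrum_rates <- function(spectrum, opportunities, metadata,
                                       level = 0.95) {
  stopifnot(inherits(spectrum, "spectrum_counts"))
  t_sum <- sum(metadata$T)
  origin <- ifelse(startsWith(SPECTRUM_CLASSES, "A:T"),
                   opportunities$at_sites, opportunities$gc_sites)
  if (any(origin <= 0 & spectrum$classes > 0))
    stop("zero opportunity sites for a class with observed events")
  out <- data.frame(class = SPECTRUM_CLASSES,
                    m = as.integer(spectrum$classes[SPECTRUM_CLASSES]),
                    origin_sites = origin,
                    denominator = origin * t_sum,
                    stringsAsFactors = FALSE)
  out$rate <- ifelse(out$denominator > 0, out$m / out$denominator, 0)
  ci <- t(mapply(function(m, d) {
    if (d <= 0) c(low = 0, high = NA_real_) else poisson_ci(m, d, level)
  }, out$m, out$denominator))
  out$ci_low <- ci[, "low"]
  out$ci_high <- ci[, "high"]
  out
}

#' Mutation rate at 4-fold degenerate sites
#'
#' Restricts the event count to base substitutions falling on 4-fold
#' degenerate third-codon positions (where every change is synonymous and
#' hence free of selection) and divides by the 4-fold site count times the
#' summed cell divisions.
#'
#' @param records Mutation-record data.frame.
#' @param fourfold Either a `site_opportunities` object or its `fourfold`
#'   data.frame (`contig`, `pos`).
#' @param metadata Per-line metadata.
#' @param level Confidence level.
#' @return A one-row `rate_estimate` data.frame (`mclass = "BPS-4fold"`).
#' @export
fourfold_rate <- function(records, fourfold, metadata, level = 0.95) {
  if (inherits(fourfold, "site_opportunities")) fourfold <- fourfold$fourfold
  if (is.null(fourfold) || nrow(fourfold) == 0L)
    stop("empty 4-fold degenerate site set")
  key <- paste(fourfold$contig, fourfold$pos)
  bps <- records[records$mclass == "BPS", , drop = FALSE]
  m <- sum(paste(bps$contig, bps$pos) %in% key)
  denominator <- nrow(fourfold) * sum(metadata$T)
  new_rate_estimate("BPS-4fold", m, denominator, m / denominator, NA_real_,
                    poisson_ci(m, denominator, level), level)
}

#' Effective population size of a single-cell-bottleneck colony cycle
#'
#' One transfer cycle grows a colony from a single cell by binary fission
#' for `g` cell divisions (population sizes 1, 2, 4, ...). The effective
#' size is the harmonic mean of those per-generation sizes,
#' `Ne = g / sum_{i=0}^{ceiling(g)-1} 2^-i`, with a fractional final
#' generation weighted by `g - floor(g)`. `Ne` approaches `g/2` for large
#' `g`, which is why daily single-colony transfers keep drift dominant.
#'
#' @param g Cell divisions per transfer cycle (may be fractional).
#' @return The effective population size (not rounded).
#' @export
effective_population_size <- function(g) {
  if (length(g) != 1L || is.na(g) || g <= 0) stop("g must be positive")
  k <- floor(g)
  frac <- g - k
  weight_sum <- if (k > 0) sum(2^-(0:(k - 1))) else 0
  if (frac > 0) weight_sum <- weight_sum + frac * 2^-k
  g / weight_sum
}
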