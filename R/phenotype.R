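#' Efficiency of plating
#'
#' `EOP = m / N`: colony-forming units on the treated plate divided by CFU
#' on the untreated control plate. Values above 1 are reported as-is.
#'
#' @param treated_cfu,reference_cfu CFU counts (vectorized).
#' @return Numeric EOP fractions.
#' @export
eop <- function(treated_cfu, reference_cfu) {
  if (any(reference_cfu <= 0)) stop("reference CFU must be positive")
  if (any(treated_cfu < 0)) stop("CFU counts must be non-negative")
  treated_cfu / reference_cfu
}

#' Minimum inhibitory concentration from a plating series
#'
#' The MIC is the lowest tested concentration at which every replicate's
#' CFU count is zero ("no visible growth" operationalized as zero colonies).
#' If growth persists at all tested concentrations, an error of class
#' `mic_above_range` is signaled.
#'
#' @param series Data.frame with columns `concentration`, `replicate`,
#'   `cfu` (and optionally `reference_cfu`), as produced by
#'   [simulate_plating()].
#' @return The MIC, on the concentration scale of the input.
#' @export
mic_from_series <- function(series) {
  stopifnot(all(c("concentration", "cfu") %in% names(series)))
  if (any(series$cfu < 0)) stop("CFU counts must be non-negative")
  all_zero <- tapply(series$cfu, series$concentration,
                     function(x) all(x == 0))
  conc <- as.numeric(names(all_zero))
  hit <- conc[all_zero]
  if (!length(hit))
    stop(errorCondition("MIC above tested concentration range",
                        class = c("mic_above_range", "error", "condition")))
  min(hit)
}

#' Exponential growth rate from a log-linear fit
#'
#' Slope of the least-squares fit of log density against time over the fit
#' window. The default window keeps points with density between 10% and 90%
#' of the curve maximum (the exponential phase); if fewer than 3 points
#' fall inside, all points are used.
#'
#' @param curve Data.frame with strictly increasing `time` (hours) and
#'   positive `density` (OD or CFU/mL).
#' @param window Optional `c(t_start, t_end)` overriding the default.
#' @param reference_rate Optional rate by which to normalize (e.g. the
#'   ancestor's), in which case the ratio is returned.
#' @return Growth rate per hour (or the normalized ratio).
#' @export
growth_rate <- function(curve, window = NULL, reference_rate = NULL) {
  stopifnot(all(c("time", "density") %in% names(curve)))
  if (any(diff(curve$time) <= 0)) stop("times must be strictly increasing")
  if (any(curve$density <= 0)) stop("densities must be positive")
  if (is.null(window)) {
    dmax <- max(curve$density)
    keep <- curve$density >= 0.1 * dmax & curve$density <= 0.9 * dmax
    if (sum(keep) < 3L) keep <- rep(TRUE, nrow(curve))
  } else {
    keep <- curve$time >= window[1] & curve$time <= window[2]
  }
  fit_data <- curve[keep, , drop = FALSE]
  if (nrow(fit_data) < 3L) stop("need at least 3 points in the fit window")
  rate <- unname(stats::coef(stats::lm(log(density) ~ time,
                                       data = fit_data))[2])
  if (!is.null(reference_rate)) rate / reference_rate else rate
}

#' MIC fold change relative to the ancestor
#'
#' @param evolved_mic,ancestral_mic MIC values (vectorized).
#' @return Fold changes `evolved / ancestral`.
#' @export
mic_fold_change <- function(evolved_mic, ancestral_mic) {
  if (any(ancestral_mic <= 0)) stop("ancestral MIC must be positive")
  evolved_mic / ancestral_mic
}
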