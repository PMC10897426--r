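#' Percentile gating of a flow sample
#'
#' Selects the bottom `low_fraction` and top `high_fraction` of events by
#' empirical rank, mirroring FACS practice of sorting the bottom/top 5% of
#' the TMRM signal. Gate sizes use floor rounding
#' (`floor(fraction * N)` events); ties are broken by event order via a
#' stable sort. Thresholds are the intensities at the rank cut-points.
#' Gating is purely rank-based; the fitted mixture model supplies
#' probabilities only (see [subpopulation_probability()]).
#'
#' @param sample a [flow_sample()] or numeric vector.
#' @param low_fraction fraction of lowest-intensity events to gate, in (0, 1).
#' @param high_fraction fraction of highest-intensity events to gate, in (0, 1).
#' @return An object of class `gate_result` with fields `low_threshold`,
#'   `high_threshold`, `low_indices`, `high_indices`, `low_fraction`,
#'   `high_fraction`, `n`. An empty gate (floor rounding at small N) yields
#'   a warning and an NA threshold.
#' @examples
#' g <- gate_percentiles(flow_sample(1:100 + 0), 0.05, 0.05)
#' g$low_threshold  # 5
#' @export
gate_percentiles <- function(sample, low_fraction = 0.05,
                             high_fraction = 0.05) {
  x <- as_intensities(sample)
  n <- length(x)
  if (!is_number(low_fraction) || low_fraction <= 0 || low_fraction >= 1) {
    stopf("low_fraction: must lie in (0, 1)")
  }
  if (!is_number(high_fraction) || high_fraction <= 0 || high_fraction >= 1) {
    stopf("high_fraction: must lie in (0, 1)")
  }
  ord <- order(x)  # stable: ties keep event order
  xs <- x[ord]
  n_low <- floor(low_fraction * n)
  n_high <- floor(high_fraction * n)
  low_indices <- ord[seq_len(n_low)]
  high_indices <- if (n_high > 0) ord[seq.int(n - n_high + 1, n)] else integer(0)
  low_threshold <- if (n_low > 0) xs[n_low] else NA_real_
  high_threshold <- if (n_high > 0) xs[n - n_high + 1] else NA_real_
  if (n_low == 0 || n_high == 0) {
    warnf("empty gate: floor(%g * %d) = 0 events; increase the sample size",
          if (n_low == 0) low_fraction else high_fraction, n)
  }
  structure(list(low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 low_indices = low_indices, high_indices = high_indices,
                 low_fraction = low_fraction, high_fraction = high_fraction,
                 n = n),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(
    "<gate_result: N = %d; low %g%% -> %d events (<= %.4g); high %g%% -> %d events (>= %.4g)>\n",
    x$n, 100 * x$low_fraction, length(x$low_indices), x$low_threshold,
    100 * x$high_fraction, length(x$high_indices), x$high_threshold))
  invisible(x)
}

#' Subpopulation probability under a fitted mixture
#'
#' The probability of a low- or high-potential cell under the fitted
#' Gaussian model: the mixture cumulative mass on the requested side of a
#' threshold, computed as the weight-averaged Gaussian CDF (tail mass at
#' the threshold, not a component posterior).
#'
#' @param fit a converged `mixture_fit` (or a [mixture_spec()]).
#' @param threshold activity threshold (a.u., finite).
#' @param side `"below"` or `"above"`.
#' @return A probability.
#' @export
subpopulation_probability <- function(fit, threshold,
                                      side = c("below", "above")) {
  side <- match.arg(side)
  if (inherits(fit, "mixture_fit") && !isTRUE(fit$converged)) {
    stopf("fit: must have converged")
  }
  if (!is_number(threshold)) stopf("threshold: must be finite")
  p_below <- sum(fit$weights * stats::pnorm(threshold, fit$means, fit$sds))
  if (side == "below") p_below else 1 - p_below
}
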