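#' Flow-cytometry intensity sample
#'
#' A labelled vector of per-event fluorescence intensities (e.g. the TMRM
#' channel, a proxy for mitochondrial membrane potential) on a positive
#' linear activity scale, in arbitrary units.
#'
#' @param intensities numeric vector of per-event intensities; must be
#'   non-empty, finite and strictly positive.
#' @param sample_id single character label for the sample.
#' @return An object of class `flow_sample` with fields `sample_id` and
#'   `intensities`.
#' @examples
#' fs <- flow_sample(c(8.2, 11.5, 9.9), "bulk")
#' length(fs$intensities)
#' @export
flow_sample <- function(intensities, sample_id = "sample") {
  if (length(intensities) == 0) {
    stopf("intensities: must be non-empty")
  }
  if (!is.numeric(intensities)) {
    stopf("intensities: must be numeric")
  }
  intensities <- as.numeric(intensities)
  if (any(!is.finite(intensities))) {
    stopf("intensities: all values must be finite (first offender at event %d)",
          which(!is.finite(intensities))[1])
  }
  if (any(intensities <= 0)) {
    stopf("intensities: all values must be > 0 (first offender at event %d)",
          which(intensities <= 0)[1])
  }
  if (length(sample_id) != 1 || !is.character(sample_id) || is.na(sample_id)) {
    stopf("sample_id: must be a single character label")
  }
  structure(list(sample_id = sample_id, intensities = intensities),
            class = "flow_sample")
}

# Accept either a flow_sample or a bare numeric vector of intensities.
as_intensities <- function(x) {
  if (inherits(x, "flow_sample")) x$intensities else as.numeric(x)
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("<flow_sample '%s': %d events, mean %.4g, range [%.4g, %.4g]>\n",
              x$sample_id, length(x$intensities), mean(x$intensities),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
length.flow_sample <- function(x) length(x$intensities)
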