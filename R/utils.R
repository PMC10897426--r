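#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from a single integer seed per call;
#' internal substreams (restarts, replicates, generations) are derived
#' deterministically from it so that adding replicates never perturbs earlier
#' ones. The derivation is a simple multiplicative hash over the seed and any
#' extra labels, reduced modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param ... further integer or character labels naming the substream.
#' @return An integer in \[0, 2^31 - 2\] usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  labels <- list(...)
  parts <- as.numeric(seed)
  for (p in labels) {
    if (is.character(p)) {
      b <- utf8ToInt(p)
      parts <- c(parts, sum(b * seq_along(b)))
    } else {
      parts <- c(parts, as.numeric(p))
    }
  }
  h <- 0
  for (p in parts) {
    # 69069: classic Marsaglia multiplier; products stay < 2^53
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h)
}

# Stable text hash for config provenance (polynomial hash mod 2^31 - 1).
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE, null = "null"))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
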