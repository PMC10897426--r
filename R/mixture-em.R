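#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Fits a k-component univariate Gaussian mixture to an intensity sample.
#' The first start is deterministic (evenly spaced sample quantiles as
#' means, pooled sd, uniform weights); the remaining `n_starts - 1` starts
#' are randomized. The fit with the highest final log-likelihood is
#' returned. The log-likelihood is asserted non-decreasing at every
#' iteration; a variance floor of `1e-6 * sd(x)` (or `1e-12` absolute for
#' constant samples) guards against likelihood singularities.
#'
#' @param sample a [flow_sample()] or numeric vector of intensities.
#' @param k number of components (>= 1); requires at least `2k` events.
#' @param tol convergence tolerance on the log-likelihood improvement
#'   (> 0); `converged` is TRUE iff the improvement fell below `tol`
#'   before `max_iter`.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of initializations (first one deterministic).
#' @param seed integer seed for the randomized restarts.
#' @return An object of class `mixture_fit` with fields `k`, `weights`,
#'   `means`, `sds` (components ordered by mean), `log_likelihood`, `bic`,
#'   `n_iter`, `converged`, `loglik_trace`, `n`, `sd_floor`.
#' @examples
#' fs <- generate_flow_sample(tmrm_bimodal_spec(), 2000, seed = 1)
#' fit <- fit_mixture(fs, k = 2)
#' fit$means
#' @export
fit_mixture <- function(sample, k, tol = 1e-8, max_iter = 500L,
                        n_starts = 5L, seed = 1L) {
  x <- as_intensities(sample)
  n <- length(x)
  if (!is_count(k)) stopf("k: must be a count >= 1")
  if (n < 2 * k) {
    stopf("input size: need at least 2k = %d events for k = %d, got %d",
          2 * k, k, n)
  }
  if (!is_number(tol) || tol <= 0) stopf("tol: must be > 0")
  if (!is_count(max_iter)) stopf("max_iter: must be a count >= 1")
  if (!is_count(n_starts)) stopf("n_starts: must be a count >= 1")

  sx <- stats::sd(x)
  sd_floor <- if (!is.finite(sx) || sx == 0) 1e-12 else 1e-6 * sx

  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) {
      em_init_quantile(x, k, sd_floor)
    } else {
      em_init_random(x, k, sd_floor, derive_seed(seed, "em-start", s))
    }
    fit <- tryCatch(
      em_gaussian(x, k, init, tol, max_iter, sd_floor),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$log_likelihood) &&
        (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stopf("mixture fit failed: no initialization produced a finite likelihood")
  }

  ord <- order(best$means)
  structure(list(
    k = k,
    weights = best$weights[ord],
    means = best$means[ord],
    sds = best$sds[ord],
    log_likelihood = best$log_likelihood,
    bic = -2 * best$log_likelihood + (3 * k - 1) * log(n),
    n_iter = best$n_iter,
    converged = best$converged,
    loglik_trace = best$loglik_trace,
    n = n,
    sd_floor = sd_floor
  ), class = "mixture_fit")
}

em_init_quantile <- function(x, k, sd_floor) {
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  pooled <- sqrt(mean((x - mean(x))^2))
  list(weights = rep(1 / k, k), means = mu,
       sds = rep(max(pooled / k, sd_floor), k))
}

em_init_random <- function(x, k, sd_floor, seed) {
  set.seed(seed)
  pooled <- sqrt(mean((x - mean(x))^2))
  mu <- sample(x, k) + stats::rnorm(k, 0, pooled / 10 + sd_floor)
  w <- stats::runif(k, 0.5, 1.5)
  list(weights = w / sum(w), means = mu,
       sds = rep(max(pooled, sd_floor), k))
}

em_gaussian <- function(x, k, init, tol, max_iter, sd_floor) {
  n <- length(x)
  w <- init$weights
  mu <- init$means
  sigma <- pmax(init$sds, sd_floor)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    logcomp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      logcomp[, j] <- log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE)
    }
    mx <- logcomp[, 1]
    if (k > 1) for (j in 2:k) mx <- pmax(mx, logcomp[, j])
    lse <- mx + log(rowSums(exp(logcomp - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) stopf("EM: non-finite log-likelihood")
    # monotonicity guard: EM must never decrease the likelihood
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
      stopf("EM: log-likelihood decreased (%.10g -> %.10g)", ll_old, ll)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- exp(logcomp - lse)
    nj <- pmax(colSums(resp), 1e-300)
    w <- nj / n
    mu <- colSums(resp * x) / nj
    dev2 <- (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2
    sigma <- pmax(sqrt(colSums(resp * dev2) / nj), sd_floor)
  }
  list(weights = w, means = mu, sds = sigma, log_likelihood = ll,
       n_iter = n_iter, converged = converged, loglik_trace = trace)
}

#' Select the number of mixture components by BIC
#'
#' Fits `k = 1..k_max` mixtures and returns the fit minimizing
#' `BIC = -2 log L + p log N` with `p = 3k - 1` free parameters; ties are
#' broken toward smaller k.
#'
#' @inheritParams fit_mixture
#' @param k_max largest component count to consider (>= 1).
#' @return The winning `mixture_fit`, with an extra `candidates` data frame
#'   (columns `k`, `log_likelihood`, `bic`, `converged`).
#' @export
select_components <- function(sample, k_max, tol = 1e-8, max_iter = 500L,
                              n_starts = 5L, seed = 1L) {
  if (!is_count(k_max)) stopf("k_max: must be a count >= 1")
  fits <- lapply(seq_len(k_max), function(k) {
    fit_mixture(sample, k, tol = tol, max_iter = max_iter,
                n_starts = n_starts, seed = seed)
  })
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(bics)]]  # which.min returns the first (smallest k) tie
  best$candidates <- data.frame(
    k = seq_len(k_max),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    bic = bics,
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  best
}

#' Mixture density of a fitted model or spec
#'
#' @param object a `mixture_fit` or [mixture_spec()].
#' @param x numeric vector of evaluation points.
#' @return Numeric vector of density values.
#' @export
mixture_density <- function(object, x) {
  d <- numeric(length(x))
  for (j in seq_along(object$weights)) {
    d <- d + object$weights[j] * stats::dnorm(x, object$means[j], object$sds[j])
  }
  d
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: k = %d, logL = %.4f, BIC = %.4f, %s in %d iter>\n",
              x$k, x$log_likelihood, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}
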