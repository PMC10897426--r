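#' Outcome-probability strata over the activity scale
#'
#' The division model draws each daughter's outcome (I: decrease, J: stay,
#' K: increase) from probabilities that may depend on the parent's current
#' activity. Strata are half-open intervals `[lower, upper)` that partition
#' `(0, Inf)`.
#'
#' @param breaks interior stratum boundaries (strictly increasing, > 0);
#'   `numeric(0)` gives a single stratum covering the whole scale.
#' @param probs matrix or data frame with one row per stratum and columns
#'   `p_I`, `p_J`, `p_K`; each row must sum to 1 within 1e-9.
#' @return A data frame with columns `lower`, `upper`, `p_I`, `p_J`, `p_K`.
#' @examples
#' division_strata(numeric(0), cbind(p_I = 1/3, p_J = 1/3, p_K = 1/3))
#' @export
division_strata <- function(breaks, probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- c("p_I", "p_J", "p_K")
  n_strata <- length(breaks) + 1
  if (nrow(probs) != n_strata || ncol(probs) != 3) {
    stopf("probs: need a %d x 3 matrix of (p_I, p_J, p_K)", n_strata)
  }
  if (length(breaks) > 0) {
    if (any(!is.finite(breaks)) || any(breaks <= 0) ||
        any(diff(breaks) <= 0)) {
      stopf("breaks: must be finite, > 0 and strictly increasing")
    }
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stopf("probs: all probabilities must be finite and >= 0")
  }
  bad <- which(abs(rowSums(probs) - 1) > 1e-9)
  if (length(bad) > 0) {
    stopf("probs: row %d does not sum to 1 within 1e-9", bad[1])
  }
  data.frame(lower = c(0, breaks), upper = c(breaks, Inf),
             p_I = probs[, 1], p_J = probs[, 2], p_K = probs[, 3])
}

#' @rdname division_strata
#' @param p_I,p_J,p_K probabilities for a single stratum spanning (0, Inf).
#' @export
uniform_strata <- function(p_I = 1 / 3, p_J = 1 / 3, p_K = 1 / 3) {
  division_strata(numeric(0), cbind(p_I = p_I, p_J = p_J, p_K = p_K))
}

#' @rdname division_strata
#' @param threshold activity boundary between the low and the bulk stratum.
#' @param low probabilities (p_I, p_J, p_K) below `threshold`; the default
#'   (0.1, 0.1, 0.8) honours Pk = 0.8 for low-potential daughters.
#' @param rest probabilities at or above `threshold`.
#' @export
low_gate_strata <- function(threshold, low = c(0.1, 0.1, 0.8),
                            rest = c(1 / 3, 1 / 3, 1 / 3)) {
  division_strata(threshold, rbind(low, rest))
}

#' Parameters of the cell-division activity-fluctuation model
#'
#' At each division a parent of activity `a` yields
#' `daughters_per_parent` daughters; each daughter independently takes one
#' of three outcomes: I, activity decreased to `max(floor, a * runif(m, 1))`;
#' J, activity unchanged; K, activity increased to `a * runif(1, n_coef)`.
#' `n_coef` is the activity-fluctuation coefficient (called t when
#' estimated): the maximal multiplicative increase per division, 1.25
#' meaning activity alters by up to ~25% per division. The lower bound `m`
#' defaults to `1 / n_coef` (symmetric multiplicative fluctuation, scale
#' preserving); the additive alternative `m = 2 - n_coef` is selectable via
#' `m_rule`. The activity floor of 1 is the scale's minimum.
#'
#' @param n_coef upper fluctuation bound t (>= 1).
#' @param m lower fluctuation bound in (0, 1]; if NULL, resolved from
#'   `m_rule`.
#' @param m_rule `"reciprocal"` (`m = 1/n_coef`) or `"linear"`
#'   (`m = 2 - n_coef`, requiring `n_coef < 2`).
#' @param strata outcome-probability strata (see [division_strata()]);
#'   default: one stratum with equal probabilities.
#' @param floor activity floor (a.u., > 0); default 1.
#' @param init_mean,init_sd mean and sd of the normal distribution for the
#'   initial parental population (see [init_parent_population()]). Defaults
#'   10 and 1.2 a.u. (coefficient of variation 0.12; see the package
#'   vignette for the calibration rationale).
#' @param daughters_per_parent daughters per division (default 2).
#' @param population_cap maximal population size; when a division exceeds
#'   it, a uniform random subsample of this size is retained (unbiased,
#'   keeps memory bounded). Default 20000.
#' @return An object of class `division_params`.
#' @export
division_params <- function(n_coef = 1.25, m = NULL,
                            m_rule = c("reciprocal", "linear"),
                            strata = uniform_strata(), floor = 1,
                            init_mean = 10, init_sd = 1.2,
                            daughters_per_parent = 2L,
                            population_cap = 20000L) {
  m_rule <- match.arg(m_rule)
  if (!is_number(n_coef) || n_coef < 1) stopf("n_coef: must be >= 1")
  if (is.null(m)) {
    m <- if (m_rule == "reciprocal") 1 / n_coef else 2 - n_coef
  }
  if (!is_number(m) || m <= 0 || m > 1) stopf("m: must lie in (0, 1]")
  if (!is_number(floor) || floor <= 0) stopf("floor: must be > 0")
  if (!is_number(init_mean)) stopf("init_mean: must be finite")
  if (!is_number(init_sd) || init_sd < 0) stopf("init_sd: must be >= 0")
  if (!is_count(daughters_per_parent)) {
    stopf("daughters_per_parent: must be a count >= 1")
  }
  if (!is_count(population_cap)) stopf("population_cap: must be a count >= 1")
  if (!is.data.frame(strata) ||
      !all(c("lower", "upper", "p_I", "p_J", "p_K") %in% names(strata))) {
    stopf("strata: must come from division_strata()")
  }
  # re-validate (strata may have been edited by hand)
  strata <- division_strata(strata$lower[-1],
                            as.matrix(strata[, c("p_I", "p_J", "p_K")]))
  structure(list(n_coef = n_coef, m = m, m_rule = m_rule, strata = strata,
                 floor = floor, init_mean = init_mean, init_sd = init_sd,
                 daughters_per_parent = as.integer(daughters_per_parent),
                 population_cap = as.integer(population_cap)),
            class = "division_params")
}

#' @export
print.division_params <- function(x, ...) {
  cat(sprintf(
    "<division_params: t = %g, m = %g (%s), floor = %g, %d daughters, cap %d>\n",
    x$n_coef, x$m, x$m_rule, x$floor, x$daughters_per_parent,
    x$population_cap))
  print(x$strata)
  invisible(x)
}

# Replace the coefficient, re-resolving m from the configured m-t relation.
set_coefficient <- function(params, n_coef) {
  division_params(n_coef = n_coef, m = NULL, m_rule = params$m_rule,
                  strata = params$strata, floor = params$floor,
                  init_mean = params$init_mean, init_sd = params$init_sd,
                  daughters_per_parent = params$daughters_per_parent,
                  population_cap = params$population_cap)
}

#' Draw the initial parental population
#'
#' Activities are drawn from `Normal(init_mean, init_sd)` — the model's
#' assumption that parental cells follow the bulk population's mean and
#' standard deviation — and clamped to the floor.
#'
#' @param params a [division_params()].
#' @param size population size (>= 1).
#' @param seed integer seed.
#' @return Numeric activity vector of length `size`, all `>= params$floor`.
#' @export
init_parent_population <- function(params, size, seed = 1L) {
  if (!inherits(params, "division_params")) {
    stopf("params: must be a division_params")
  }
  if (!is_count(size)) stopf("size: must be a count >= 1")
  set.seed(derive_seed(seed, "init"))
  pmax(stats::rnorm(size, params$init_mean, params$init_sd), params$floor)
}

#' Daughter activity under a given outcome and factor
#'
#' Applies the division rule directly: outcome I gives
#' `max(floor, a * factor)` with `factor` in `[m, 1]`; J leaves the
#' activity unchanged; K gives `a * factor` with `factor` in `[1, n_coef]`.
#' Vectorized over `a`, `outcome`, `factor`.
#'
#' @param a parent activity (>= floor).
#' @param outcome `"I"`, `"J"` or `"K"`.
#' @param factor the uniform draw for outcomes I and K (ignored for J).
#' @param params a [division_params()].
#' @return Daughter activity.
#' @examples
#' p <- division_params(n_coef = 1.25)
#' daughter_activity(10, "I", 0.8, p)  # 8
#' @export
daughter_activity <- function(a, outcome, factor = NA_real_, params) {
  if (!inherits(params, "division_params")) {
    stopf("params: must be a division_params")
  }
  nn <- max(length(a), length(outcome), length(factor))
  a <- rep_len(as.numeric(a), nn)
  outcome <- rep_len(as.character(outcome), nn)
  factor <- rep_len(as.numeric(factor), nn)
  if (any(!is.finite(a)) || any(a < params$floor)) {
    stopf("a: activities must be finite and >= the floor (%g)", params$floor)
  }
  if (!all(outcome %in% c("I", "J", "K"))) {
    stopf("outcome: must be one of I, J, K")
  }
  iI <- outcome == "I"
  iK <- outcome == "K"
  if (any(iI) && (any(!is.finite(factor[iI])) |
                  any(factor[iI] < params$m - 1e-12) ||
                  any(factor[iI] > 1 + 1e-12))) {
    stopf("contract violation: outcome I requires factor in [m, 1] = [%g, 1]",
          params$m)
  }
  if (any(iK) && (any(!is.finite(factor[iK])) ||
                  any(factor[iK] < 1 - 1e-12) ||
                  any(factor[iK] > params$n_coef + 1e-12))) {
    stopf("contract violation: outcome K requires factor in [1, n] = [1, %g]",
          params$n_coef)
  }
  out <- a
  out[iI] <- pmax(params$floor, a[iI] * factor[iI])
  out[iK] <- a[iK] * factor[iK]
  out
}

# One synchronous division of the whole population. Internal workhorse
# shared by simulate_division() and the lineage recorder.
divide_once <- function(parents, params, seed, detail = FALSE) {
  set.seed(derive_seed(seed, "division"))
  d <- params$daughters_per_parent
  a <- rep(parents, each = d)
  parent_index <- rep(seq_along(parents), each = d)
  nn <- length(a)
  stratum <- findInterval(a, params$strata$lower)
  u <- stats::runif(nn)
  p_i <- params$strata$p_I[stratum]
  p_j <- params$strata$p_J[stratum]
  outcome <- rep("K", nn)
  outcome[u < p_i + p_j] <- "J"
  outcome[u < p_i] <- "I"
  factor <- rep(1, nn)
  iI <- outcome == "I"
  iK <- outcome == "K"
  factor[iI] <- stats::runif(sum(iI), params$m, 1)
  factor[iK] <- stats::runif(sum(iK), 1, params$n_coef)
  activity <- a
  activity[iI] <- pmax(params$floor, a[iI] * factor[iI])
  activity[iK] <- a[iK] * factor[iK]
  if (nn > params$population_cap) {
    keep <- sort(sample.int(nn, params$population_cap))
    activity <- activity[keep]
    parent_index <- parent_index[keep]
    outcome <- outcome[keep]
    factor <- factor[keep]
  }
  if (detail) {
    list(activity = activity,
         detail = data.frame(parent_index = parent_index, outcome = outcome,
                             factor = factor, activity = activity,
                             stringsAsFactors = FALSE))
  } else {
    list(activity = activity, detail = NULL)
  }
}

#' Simulate one cell division of a population
#'
#' Every parent yields `daughters_per_parent` daughters. Each daughter
#' independently draws its outcome (I/J/K) from the probabilities of the
#' stratum containing the parent's activity (stratum membership is
#' evaluated on the parent at the moment of division), then its factor from
#' the matching uniform interval. If the daughter count exceeds
#' `population_cap` a uniform random subsample is retained.
#'
#' @param parents non-empty numeric activity vector (all >= floor).
#' @param params a [division_params()].
#' @param seed integer seed.
#' @return Numeric vector of daughter activities.
#' @export
simulate_division <- function(parents, params, seed = 1L) {
  if (!inherits(params, "division_params")) {
    stopf("params: must be a division_params")
  }
  parents <- as_intensities(parents)
  if (length(parents) == 0) stopf("parents: must be non-empty")
  if (any(!is.finite(parents)) || any(parents < params$floor)) {
    stopf("parents: all activities must be finite and >= the floor (%g)",
          params$floor)
  }
  divide_once(parents, params, seed)$activity
}

#' Simulate successive divisions of a population
#'
#' Iterates [simulate_division()] for `n_generations` synchronous
#' divisions, recording every generation including generation 0 (the
#' initial population). Deterministic given the seed; each generation uses
#' a derived substream.
#'
#' @param initial non-empty activity vector (all >= floor); generation 0.
#' @param params a [division_params()].
#' @param n_generations number of divisions (>= 0).
#' @param seed integer seed.
#' @param record_outcomes if TRUE, per-daughter outcome/factor records are
#'   kept (used by [generate_lineage_dataset()]).
#' @return An object of class `population_trajectory`: list with
#'   `generations` (list of activity vectors, length `n_generations + 1`),
#'   `params`, `seed`, and (optionally) `outcome_records`.
#' @export
simulate_generations <- function(initial, params, n_generations, seed = 1L,
                                 record_outcomes = FALSE) {
  if (!inherits(params, "division_params")) {
    stopf("params: must be a division_params")
  }
  initial <- as_intensities(initial)
  if (length(initial) == 0) stopf("initial: must be non-empty")
  if (any(!is.finite(initial)) || any(initial < params$floor)) {
    stopf("initial: all activities must be finite and >= the floor (%g)",
          params$floor)
  }
  if (!is_count(n_generations, min = 0)) {
    stopf("n_generations: must be a count >= 0")
  }
  gens <- vector("list", n_generations + 1)
  gens[[1]] <- initial
  records <- if (record_outcomes) vector("list", n_generations) else NULL
  for (g in seq_len(n_generations)) {
    step <- divide_once(gens[[g]], params, derive_seed(seed, "generation", g),
                        detail = record_outcomes)
    gens[[g + 1]] <- step$activity
    if (record_outcomes) records[[g]] <- step$detail
  }
  structure(list(generations = gens, params = params, seed = seed,
                 outcome_records = records),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("<population_trajectory: %d generations (seed %d)>\n",
              length(x$generations) - 1L, x$seed))
  print(summary(x))
  invisible(x)
}

#' Per-generation summary of a trajectory
#'
#' @param object a `population_trajectory`.
#' @param ... unused.
#' @return Data frame with columns `generation`, `n_cells`, `mean`, `sd`,
#'   `p5`, `p95`.
#' @export
summary.population_trajectory <- function(object, ...) {
  g <- object$generations
  data.frame(
    generation = seq_along(g) - 1L,
    n_cells = vapply(g, length, integer(1)),
    mean = vapply(g, mean, numeric(1)),
    sd = vapply(g, stats::sd, numeric(1)),
    p5 = vapply(g, function(v) unname(stats::quantile(v, 0.05)), numeric(1)),
    p95 = vapply(g, function(v) unname(stats::quantile(v, 0.95)), numeric(1))
  )
}
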