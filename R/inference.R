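#' Distance between two activity distributions
#'
#' The primary metric mirrors the model's estimation criterion — the
#' absolute difference in mean activity, scaled by the reference mean:
#' `|mean(x) - mean(y)| / mean(y)`. The secondary `"ks"` metric is the
#' two-sample Kolmogorov-Smirnov statistic, for distribution-shape
#' comparisons.
#'
#' @param x activity vector or [flow_sample()] (the progeny / comparison).
#' @param y activity vector or [flow_sample()] (the reference / parental).
#' @param metric `"relative-mean"` or `"ks"`.
#' @return A non-negative number.
#' @examples
#' distribution_distance(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
distribution_distance <- function(x, y, metric = c("relative-mean", "ks")) {
  metric <- match.arg(metric)
  x <- as_intensities(x)
  y <- as_intensities(y)
  if (length(x) == 0 || length(y) == 0) stopf("x, y: must be non-empty")
  if (metric == "relative-mean") {
    abs(mean(x) - mean(y)) / mean(y)
  } else {
    unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  }
}

#' Divisions needed for gated low-potential progeny to regain the parental
#' distribution
#'
#' Gates the bottom `gate_fraction` of the parental sample, then, for each
#' replicate, simulates successive divisions of the gated subset under the
#' fluctuation model and measures its distance to the full parental
#' distribution at every generation. The first generation whose distance
#' falls within `tolerance` is that replicate's divisions-to-convergence;
#' the report's headline value is the median across replicates (the
#' distribution over replicates is discrete and can be skewed).
#'
#' @param parental a [flow_sample()] or activity vector (the bulk
#'   population).
#' @param gate_fraction bottom fraction to gate, in (0, 1).
#' @param params a [division_params()].
#' @param max_generations number of divisions to simulate (>= 1).
#' @param tolerance convergence tolerance on the distance (> 0).
#' @param metric distance metric, see [distribution_distance()].
#' @param n_reps number of independent replicates.
#' @param seed integer seed; replicates use derived substreams.
#' @return An object of class `convergence_report` with fields `metric`,
#'   `tolerance`, `per_generation_distance` (median across replicates, one
#'   entry per generation 1..`max_generations`), `distances` (replicate x
#'   generation matrix), `divisions_to_convergence` (median; NA if the
#'   median replicate never converges), `per_rep_divisions`, `n_reps`,
#'   `max_generations`, `gate_fraction`, `seed`.
#' @export
regeneration_analysis <- function(parental, gate_fraction = 0.05, params,
                                  max_generations = 6L, tolerance = 0.05,
                                  metric = c("relative-mean", "ks"),
                                  n_reps = 50L, seed = 1L) {
  metric <- match.arg(metric)
  if (!inherits(params, "division_params")) {
    stopf("params: must be a division_params")
  }
  if (!is_count(max_generations)) stopf("max_generations: must be >= 1")
  if (!is_number(tolerance) || tolerance <= 0) stopf("tolerance: must be > 0")
  if (!is_count(n_reps)) stopf("n_reps: must be >= 1")
  x <- as_intensities(parental)
  n <- length(x)
  n_low <- floor(gate_fraction * n)
  if (!is_number(gate_fraction) || gate_fraction <= 0 || gate_fraction >= 1) {
    stopf("gate_fraction: must lie in (0, 1)")
  }
  if (n_low < 1) {
    stopf(paste0("empty gate: floor(%g * %d) = 0 events; ",
                 "provide a larger parental sample"), gate_fraction, n)
  }
  low <- x[order(x)[seq_len(n_low)]]
  if (any(low < params$floor)) {
    stopf("gated subset contains activities below the floor (%g)",
          params$floor)
  }

  distances <- matrix(NA_real_, n_reps, max_generations)
  per_rep <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    traj <- simulate_generations(low, params, max_generations,
                                 seed = derive_seed(seed, "rep", r))
    for (g in seq_len(max_generations)) {
      distances[r, g] <- distribution_distance(traj$generations[[g + 1]], x,
                                               metric = metric)
    }
    hit <- which(distances[r, ] <= tolerance)
    if (length(hit) > 0) per_rep[r] <- hit[1]
  }
  med <- stats::median(ifelse(is.na(per_rep), Inf, per_rep))
  structure(list(
    metric = metric,
    tolerance = tolerance,
    per_generation_distance = apply(distances, 2, stats::median),
    distances = distances,
    divisions_to_convergence = if (is.finite(med)) med else NA_real_,
    per_rep_divisions = per_rep,
    n_reps = n_reps,
    max_generations = as.integer(max_generations),
    gate_fraction = gate_fraction,
    seed = seed
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  med <- x$divisions_to_convergence
  cat(sprintf(
    "<convergence_report: %s metric, tol %g, %d reps; median divisions = %s>\n",
    x$metric, x$tolerance, x$n_reps,
    if (is.na(med)) "not reached" else format(med)))
  cat("median distance per generation:",
      paste(sprintf("%.4f", x$per_generation_distance), collapse = " "), "\n")
  invisible(x)
}

#' Tidy per-replicate distances
#'
#' @param x a `convergence_report`.
#' @param ... unused.
#' @return Data frame with columns `rep`, `generation`, `distance`.
#' @export
as.data.frame.convergence_report <- function(x, ...) {
  data.frame(
    rep = rep(seq_len(x$n_reps), times = x$max_generations),
    generation = rep(seq_len(x$max_generations), each = x$n_reps),
    distance = as.vector(x$distances)
  )
}

#' Estimate the activity-fluctuation coefficient by simulation-based grid
#' search
#'
#' For each candidate coefficient t on the grid (with the lower bound m
#' re-resolved from the configured m-t relation), simulates `n_reps`
#' trajectories starting from the bottom-gated parental subset and scores
#' the candidate by the mean, over generations and replicates, of the
#' absolute difference between the simulated and the observed per-
#' generation mean activities — the model's own absolute-mean-difference
#' criterion. Replicates use common random numbers across grid points
#' (identical substreams), so candidates are compared on the same draws.
#'
#' @param parental a [flow_sample()] or activity vector.
#' @param observed numeric vector of observed daughter-population mean
#'   activities, one per generation (generation 1 first).
#' @param params_template a [division_params()]; everything except the
#'   coefficient (and m) is taken from it.
#' @param grid candidate t values (all >= 1), default `seq(1, 1.6, 0.05)`.
#' @param n_reps simulation replicates per candidate.
#' @param gate_fraction bottom fraction of the parental sample used as the
#'   starting population.
#' @param seed integer seed.
#' @return An object of class `estimation_result` with fields `t_hat`,
#'   `grid`, `objective` (same length as `grid`), `n_reps`, `seed`.
#'   Ties in the objective resolve to the smallest t.
#' @export
estimate_fluctuation_coefficient <- function(parental, observed,
                                             params_template,
                                             grid = seq(1, 1.6, by = 0.05),
                                             n_reps = 20L,
                                             gate_fraction = 0.05,
                                             seed = 1L) {
  if (!inherits(params_template, "division_params")) {
    stopf("params_template: must be a division_params")
  }
  if (length(grid) == 0) stopf("grid: must be non-empty")
  if (any(!is.finite(grid)) || any(grid < 1)) {
    stopf("grid: all candidates must be >= 1")
  }
  observed <- as.numeric(observed)
  if (length(observed) < 1 || any(!is.finite(observed))) {
    stopf("observed: need finite mean activities for >= 1 generation")
  }
  if (!is_count(n_reps)) stopf("n_reps: must be >= 1")
  x <- as_intensities(parental)
  n_low <- floor(gate_fraction * length(x))
  if (n_low < 1) {
    stopf("empty gate: provide a larger parental sample")
  }
  low <- x[order(x)[seq_len(n_low)]]
  n_gen <- length(observed)

  objective <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p_t <- set_coefficient(params_template, grid[i])
    acc <- 0
    for (r in seq_len(n_reps)) {
      # common random numbers: the rep substream does not depend on t
      traj <- simulate_generations(low, p_t, n_gen,
                                   seed = derive_seed(seed, "rep", r))
      sim_means <- vapply(traj$generations[-1], mean, numeric(1))
      acc <- acc + sum(abs(sim_means - observed))
    }
    objective[i] <- acc / (n_reps * n_gen)
  }
  pick <- order(objective, grid)[1]
  structure(list(t_hat = grid[pick], grid = grid, objective = objective,
                 n_reps = n_reps, gate_fraction = gate_fraction, seed = seed),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result: t_hat = %g (grid %g..%g, %d points, %d reps)>\n",
              x$t_hat, min(x$grid), max(x$grid), length(x$grid), x$n_reps))
  invisible(x)
}
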