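test_that("distribution distances match hand arithmetic", {
  x <- c(1, 2, 3)
  expect_equal(distribution_distance(x, x), 0)
  expect_equal(distribution_distance(x, x, metric = "ks"), 0)
  expect_equal(distribution_distance(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_equal(distribution_distance(runif(50, 0, 1), runif(50, 5, 6),
                                     metric = "ks"), 1)
  expect_error(distribution_distance(x, numeric(0)), "non-empty")
  expect_error(distribution_distance(x, x, metric = "wasserstein"))
})

test_that("frozen dynamics (m = n = 1) keep the distance at its initial value", {
  fs <- bimodal_sample(4000, seed = 3)
  p <- division_params(n_coef = 1, m = 1, population_cap = 2000000L)
  rep_out <- regeneration_analysis(fs, 0.05, p, max_generations = 4,
                                   tolerance = 0.05, n_reps = 5, seed = 1)
  d0 <- distribution_distance(fs$intensities[order(fs$intensities)[1:200]],
                              fs$intensities)
  expect_true(all(abs(rep_out$distances - d0) < 1e-12))
  expect_true(is.na(rep_out$divisions_to_convergence))
  expect_true(all(is.na(rep_out$per_rep_divisions)))
})

test_that("the convergence report is complete and self-consistent", {
  p <- low_lineage_params()
  parental <- init_parent_population(p, 5000, seed = 2)
  rep_out <- regeneration_analysis(parental, 0.05, p, max_generations = 5,
                                   tolerance = 0.05, n_reps = 10, seed = 2)
  expect_identical(dim(rep_out$distances), c(10L, 5L))
  expect_length(rep_out$per_generation_distance, 5)
  expect_true(all(rep_out$distances >= 0))
  # divisions_to_convergence is the first generation within tolerance
  for (r in 1:10) {
    hit <- which(rep_out$distances[r, ] <= 0.05)
    expect_identical(rep_out$per_rep_divisions[r],
                     if (length(hit)) as.numeric(hit[1]) else NA_real_)
  }
  td <- as.data.frame(rep_out)
  expect_identical(nrow(td), 50L)
  expect_equal(td$distance[td$rep == 3], rep_out$distances[3, ])
})

test_that("an empty gate raises an instructive error", {
  p <- low_lineage_params()
  expect_error(regeneration_analysis(runif(10, 5, 10), 0.05, p, n_reps = 2),
               "larger parental sample")
})

test_that("convergence, once reached, persists for the following generation", {
  p <- low_lineage_params()
  parental <- init_parent_population(p, 10000, seed = 3)
  rep_out <- regeneration_analysis(parental, 0.05, p, max_generations = 6,
                                   tolerance = 0.05, n_reps = 25, seed = 3)
  reached <- which(!is.na(rep_out$per_rep_divisions) &
                     rep_out$per_rep_divisions < 6)
  expect_gt(length(reached), 0)
  next_ok <- vapply(reached, function(r) {
    g <- rep_out$per_rep_divisions[r]
    rep_out$distances[r, g + 1] <= 2 * rep_out$tolerance
  }, logical(1))
  expect_gte(mean(next_ok), 0.8)
})

test_that("more reactive fluctuation converges no slower (sweep over t)", {
  # restricted to coefficients whose per-division mean step stays below the
  # tolerance band; at larger t a single division can overshoot the band
  # entirely and divisions-to-convergence stops being monotone
  p <- low_lineage_params()
  parental <- init_parent_population(p, 5000, seed = 4)
  meds <- vapply(c(1.05, 1.1, 1.25), function(t) {
    out <- regeneration_analysis(parental, 0.05, low_lineage_params(t = t),
                                 max_generations = 25, tolerance = 0.05,
                                 n_reps = 15, seed = 9)
    med <- out$divisions_to_convergence
    if (is.na(med)) Inf else med
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
  # and stricter tolerance never converges faster
  loose <- regeneration_analysis(parental, 0.05, p, max_generations = 12,
                                 tolerance = 0.10, n_reps = 15, seed = 9)
  strict <- regeneration_analysis(parental, 0.05, p, max_generations = 12,
                                  tolerance = 0.02, n_reps = 15, seed = 9)
  l <- loose$divisions_to_convergence
  s <- strict$divisions_to_convergence
  expect_lte(if (is.na(l)) Inf else l, if (is.na(s)) Inf else s)
})

test_that("the objective is zero at t = 1 for self-matching observed means", {
  fs <- bimodal_sample(10000, seed = 1)
  g <- gate_percentiles(fs, 0.05, 0.05)
  low <- fs$intensities[g$low_indices]
  # symmetric outcomes, m-rule reciprocal: at t = 1 all factors are 1 and
  # duplicated daughters preserve the mean exactly (cap never engages)
  tmpl <- division_params(strata = uniform_strata(0.25, 0.5, 0.25),
                          population_cap = 2000000L)
  observed <- rep(mean(low), 4)
  est <- estimate_fluctuation_coefficient(fs, observed, tmpl,
                                          grid = c(1, 1.1, 1.2),
                                          n_reps = 3, seed = 5)
  expect_equal(est$t_hat, 1)
  expect_lt(est$objective[1], 1e-10)
  expect_true(all(est$objective >= 0))
  expect_length(est$objective, 3)
})

test_that("the simulator's own trajectories recover the generating coefficient", {
  fs <- bimodal_sample(10000, seed = 1)
  g <- gate_percentiles(fs, 0.05, 0.05)
  low <- fs$intensities[g$low_indices]
  tmpl <- low_lineage_params()
  truth <- low_lineage_params(t = 1.3)
  traj <- simulate_generations(low, truth, 4, seed = 1234)
  observed <- vapply(traj$generations[-1], mean, numeric(1))
  est <- estimate_fluctuation_coefficient(fs, observed, tmpl,
                                          grid = seq(1, 1.5, by = 0.05),
                                          n_reps = 20, seed = 99)
  expect_equal(est$t_hat, 1.3)
  expect_true(est$t_hat %in% est$grid)
  expect_equal(est$objective[which(est$grid == est$t_hat)], min(est$objective))
})

test_that("grid candidates below 1 are rejected", {
  fs <- bimodal_sample(1000, seed = 1)
  tmpl <- low_lineage_params()
  expect_error(
    estimate_fluctuation_coefficient(fs, 5, tmpl, grid = c(0.9, 1.1)),
    ">= 1")
  expect_error(
    estimate_fluctuation_coefficient(fs, 5, tmpl, grid = numeric(0)),
    "non-empty")
})
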