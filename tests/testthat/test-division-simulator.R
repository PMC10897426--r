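test_that("division_params validates bounds, strata and floor", {
  expect_error(division_params(n_coef = 0.9), "n_coef")
  expect_error(division_params(m = 1.2), "m:")
  expect_error(division_params(floor = 0), "floor")
  expect_error(division_params(strata = uniform_strata(0.5, 0.5, 0.1)),
               "sum to 1")
  p <- division_params(n_coef = 1.25)
  expect_equal(p$m, 0.8)  # reciprocal rule
  expect_equal(division_params(n_coef = 1.25, m_rule = "linear")$m, 0.75)
})

test_that("strata intervals partition the positive axis", {
  s <- low_gate_strata(2.5)
  expect_equal(s$lower, c(0, 2.5))
  expect_equal(s$upper, c(2.5, Inf))
  expect_error(division_strata(c(3, 2), rbind(c(1, 0, 0), c(1, 0, 0),
                                              c(1, 0, 0))),
               "increasing")
})

test_that("initial population is a clamped normal, deterministic under seed", {
  p0 <- division_params(init_mean = 10, init_sd = 0)
  expect_identical(init_parent_population(p0, 5, seed = 1), rep(10, 5))
  pf <- division_params(init_mean = 0.5, init_sd = 0)
  expect_identical(init_parent_population(pf, 5, seed = 1), rep(1, 5))
  p <- division_params(init_mean = 10, init_sd = 2)
  x <- init_parent_population(p, 100000, seed = 9)
  expect_lt(abs(mean(x) - 10), 0.05)  # clamping at floor 1 is negligible
  expect_identical(x, init_parent_population(p, 100000, seed = 9))
})

test_that("daughter_activity applies the printed rule and the floor", {
  p <- division_params(n_coef = 1.25, m = 0.5)
  expect_equal(daughter_activity(10, "I", 0.8, p), 8)
  expect_equal(daughter_activity(1.1, "I", 0.5, p), 1)  # max(1, 0.55)
  expect_equal(daughter_activity(10, "J", NA, p), 10)
  expect_equal(daughter_activity(10, "K", 1.2, p), 12)
})

test_that("factors outside the outcome interval violate the contract", {
  p <- division_params(n_coef = 1.25, m = 0.8)
  expect_error(daughter_activity(10, "I", 0.5, p), "contract violation")
  expect_error(daughter_activity(10, "K", 1.5, p), "contract violation")
  expect_error(daughter_activity(10, "X", 1, p), "outcome")
  expect_error(daughter_activity(0.5, "J", NA, p), "floor")
})

test_that("p_J = 1 gives identity dynamics; m = n = 1 freezes all factors", {
  pj <- division_params(strata = uniform_strata(0, 1, 0),
                        population_cap = 10000L)
  parents <- c(2, 3, 7)
  expect_identical(sort(simulate_division(parents, pj, seed = 1)),
                   sort(rep(parents, each = 2)))
  pfrozen <- division_params(n_coef = 1, m = 1, population_cap = 10000L)
  traj <- simulate_generations(c(2, 3, 7), pfrozen, 3, seed = 1)
  for (g in 1:3) {
    expect_identical(sort(unique(traj$generations[[g + 1]])), c(2, 3, 7))
  }
})

test_that("Monte-Carlo daughter mean matches the closed form within 3 se", {
  settings <- list(
    list(a = 10, p = c(0, 0, 1), m = 0.8, t = 1.25),
    list(a = 10, p = c(1, 0, 0), m = 0.8, t = 1.25),  # a*m = 8 >= 1: no floor
    list(a = 5, p = c(0.1, 0.1, 0.8), m = 0.8, t = 1.25),
    list(a = 20, p = c(0.3, 0.3, 0.4), m = 0.5, t = 1.5)
  )
  for (s in settings) {
    p <- division_params(n_coef = s$t, m = s$m,
                         strata = uniform_strata(s$p[1], s$p[2], s$p[3]),
                         population_cap = 2000000L, daughters_per_parent = 2L)
    d <- simulate_division(rep(s$a, 5e5), p, seed = 77)
    mu <- expected_daughter_mean(s$a, s$p, s$m, s$t)
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - mu), 3 * se + 1e-12)
  }
})

test_that("no activity ever drops below the floor", {
  p <- division_params(n_coef = 1.4, m = 0.3,
                       strata = uniform_strata(0.6, 0.1, 0.3),
                       init_mean = 2, init_sd = 1, population_cap = 50000L)
  init <- init_parent_population(p, 2000, seed = 4)
  traj <- simulate_generations(init, p, 6, seed = 4)
  expect_true(all(vapply(traj$generations,
                         function(g) min(g) >= p$floor, logical(1))))
})

test_that("trajectories are deterministic under seed and capped at the limit", {
  p <- low_lineage_params(population_cap = 3000L)
  init <- rep(c(2, 2.5), 1000)
  a <- simulate_generations(init, p, 3, seed = 6)
  b <- simulate_generations(init, p, 3, seed = 6)
  expect_identical(a$generations, b$generations)
  expect_identical(length(a$generations[[2]]), 3000L)  # 4000 capped to 3000
  c <- simulate_generations(init, p, 3, seed = 7)
  expect_false(identical(a$generations[[2]], c$generations[[2]]))
})

test_that("stratum membership follows the parent's activity at division", {
  # below the break every daughter increases (p_K = 1, t large); above it
  # every daughter decreases (p_I = 1); one division separates them exactly
  s <- division_strata(5, rbind(c(0, 0, 1), c(1, 0, 0)))
  p <- division_params(n_coef = 1.5, m = 0.5, strata = s,
                       population_cap = 10000L)
  d_low <- simulate_division(rep(4, 500), p, seed = 3)
  expect_true(all(d_low >= 4))
  d_high <- simulate_division(rep(8, 500), p, seed = 3)
  expect_true(all(d_high <= 8))
})

test_that("a gated low population drifts upward when p_K > p_I and t > 1", {
  fs <- bimodal_sample(4000, seed = 5)
  g <- gate_percentiles(fs, 0.05, 0.05)
  low <- fs$intensities[g$low_indices]
  p <- division_params(n_coef = 1.25,
                       strata = low_gate_strata(g$low_threshold))
  gains <- vapply(1:20, function(r) {
    traj <- simulate_generations(low, p, 3, seed = r)
    mean(traj$generations[[4]]) - mean(low)
  }, numeric(1))
  expect_gt(mean(gains > 0), 0.95)
})
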