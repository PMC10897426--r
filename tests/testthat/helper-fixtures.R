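# Shared fixtures, built in code at test time.

bimodal_sample <- function(size = 10000, seed = 1) {
  generate_flow_sample(tmrm_bimodal_spec(), size, seed = seed,
                       sample_id = "bimodal")
}

# Lineage reading of Pk = 0.8: every simulated cell descends from a
# low-potential parent, so the low-stratum probabilities apply throughout.
low_lineage_params <- function(t = 1.25, ...) {
  division_params(n_coef = t, strata = uniform_strata(0.1, 0.1, 0.8), ...)
}

# Expected daughter activity for a single stratum when the floor is inactive
expected_daughter_mean <- function(a, p, m, t) {
  a * (p[1] * (1 + m) / 2 + p[2] + p[3] * (1 + t) / 2)
}
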