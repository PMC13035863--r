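# Shared parameter sets and small builders used across the suite.

# printed group + subject parameters of the moderately metastatic cohort's
# "mouse 9" (surgery counterfactual scenario)
mouse9_params <- function() {
  metastatic_params(a_PT = 0.032, a_m = 0.032, K = 5000, mu = 0.016,
                    chi = 0.400, vartheta = 0.011, X0 = 3)
}

# a small, quick metastasis instance for oracle comparisons
small_met_params <- function() {
  metastatic_params(a_PT = 0.1, a_m = 0.1, K = 2000, mu = 0.05, chi = 0.3,
                    vartheta = 0.1, X0 = 1)
}

# a fast optimizer configuration for tests
quick_opt <- function(seed = 1L, swarm = 20, iters = 60) {
  optimizer_config(swarm_size = swarm, max_iterations = iters, restarts = 1,
                   seed = seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual / expected - 1)), tol))
}
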