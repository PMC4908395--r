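# Shared fixtures: reference parameter sets and quiet instruments.

noiseless_instrument <- function(seed = 1L)
  lox_instrument(noise_sd = 0, seed = seed)

# Default stopped-flow designs used across tests (concentrations in M)
lactate_series <- c(0.25, 0.5, 1, 2, 5, 10) * 1e-3
o2_series <- c(60, 125, 250, 500) * 1e-6

# A random feasible (k3, k5, k7, o2) set for property-style loops
random_rate_set <- function() {
  list(k3 = stats::runif(1, 5, 500),
       k5 = stats::runif(1, 5, 500),
       k7 = stats::runif(1, 5e4, 5e6),
       o2 = stats::runif(1, 5e-5, 1e-3))
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
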