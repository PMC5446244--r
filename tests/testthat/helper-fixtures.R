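# Shared fixtures, built lazily and memoized so expensive simulations run
# once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 15-unit network tutored by the smooth random protocol (the standard
# learning fixture: structure recovery, probes, perturbations)
trained_15 <- function() {
  fixture("trained_15", function() {
    p <- rate_params(15)
    W0 <- random_weights(15, seed = 101)
    proto <- make_training_protocol("sinusoids", 15, cycle_length = 500,
                                    cycles = 20, seed = 1)
    run <- train_network(W0, proto, plasticity_params(), p)
    list(params = p, run = run)
  })
}

# 10-unit handcrafted sequence network speed scan (theory + range)
handcrafted_scan <- function() {
  fixture("handcrafted_scan", function() {
    p <- rate_params(10)
    W <- build_sequence_weights(10, eta = 0.1)
    x_hat <- seq(0.3, 0.9, by = 0.1)
    scan_switch_times(p, W, xin = x_hat * (1 - 0.1), eta = 0.1)
  })
}
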