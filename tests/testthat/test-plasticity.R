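test_that("low-pass trace follows its first-order step response", {
  xb <- 0
  for (k in 1:3000) xb <- lowpass_update(xb, 1, 0.001, 3)
  expect_equal(xb, 1 - exp(-1), tolerance = 1e-3)   # t = tau_w
  expect_equal(lowpass_update(0.4, 0.4, 0.01, 3), 0.4)
  expect_error(lowpass_update(0, 1, -0.1, 3), "positive")
})

test_that("anti-Hebbian flow matches its closed-form solutions", {
  pl <- plasticity_params(alpha1 = 0.05, alpha2 = 0.02, tau_w = 3)
  n <- 3
  # presynaptic trace zero: column untouched
  W <- matrix(-0.5, n, n); diag(W) <- 0
  W2 <- weight_update(W, x = c(1, 0, 0), x_bar = c(1, 0, 1), dt = 0.1, pl)
  expect_equal(W2[, 2], W[, 2])
  # co-active pair: W -> 0 as W0 * exp(-alpha1 t)
  w <- -0.8
  for (k in 1:1000)
    w <- weight_update(matrix(w, 1, 1), 1, 1, 0.02, pl)[1, 1]
  expect_equal(w, -0.8 * exp(-0.05 * 20), tolerance = 1e-3)
  # silent postsynaptic unit: W -> -1 as -1 + (W0 + 1) exp(-alpha2 t)
  w <- -0.2
  for (k in 1:1000)
    w <- weight_update(matrix(w, 1, 1), 0, 1, 0.02, pl)[1, 1]
  expect_equal(w, -1 + 0.8 * exp(-0.02 * 20), tolerance = 1e-3)
})

test_that("weights stay inside [-1, 0] under arbitrary activity", {
  pl <- plasticity_params()
  set.seed(42)
  W <- random_weights(6, seed = 3)
  for (k in 1:500) {
    W <- weight_update(W, runif(6), runif(6), 0.1, pl)
    expect_true(all(W >= -1 & W <= 0))
  }
})

test_that("plasticity parameter contracts hold", {
  expect_error(plasticity_params(alpha1 = 0), "positive")
  expect_warning(plasticity_params(tau_w = 30, dwell_time = 20), "dwell")
  expect_silent(plasticity_params(tau_w = 3, dwell_time = 20))
})

test_that("pulse tutoring recovers a seeded random cyclic order exactly", {
  p <- rate_params(15)
  W0 <- random_weights(15, seed = 11)
  proto <- make_training_protocol("pulses", 15, cycle_length = 15 * 20,
                                  cycles = 10, tau_y = 20, seed = 42)
  run <- train_network(W0, proto, plasticity_params(), p)
  sc <- weight_structure_score(run$W, proto$schedule$order)
  expect_equal(sc$accuracy, 1)
  expect_true(all(run$W >= -1 & run$W <= 0))
  # taught order realized in the final cycle is the pulse order (up to
  # cyclic rotation)
  ord <- run$taught_order
  expect_setequal(ord, proto$schedule$order)
  k <- match(ord[1], proto$schedule$order)
  rot <- proto$schedule$order[((k - 1 + seq_along(ord) - 1) %% 15) + 1]
  expect_equal(ord, rot)
})

test_that("tonic probes express a short sequence before and the taught cycle after learning", {
  fx <- trained_15()
  run <- fx$run
  expect_gte(length(run$probe_before$order), 1)
  # after training the expressed order follows the taught cycle
  link <- learned_link_strength(run$W, run$taught_order)
  sim <- simulate_rate_network(fx$params, run$W,
                               protocol_tonic(15, 0.5 * link),
                               duration = 300)
  expect_true(follows_cycle(sim$trace, run$taught_order))
})

test_that("a second tutor overwrites the stored sequence", {
  fx <- trained_15()
  p <- fx$params
  proto2 <- make_training_protocol("sinusoids", 15, cycle_length = 500,
                                   cycles = 20, seed = 2)
  run2 <- train_network(fx$run$W, proto2, plasticity_params(), p)
  first <- weight_structure_score(run2$W, fx$run$taught_order)$accuracy
  second <- weight_structure_score(run2$W, run2$taught_order)$accuracy
  expect_equal(second, 1)
  expect_lt(first, 1)
})

test_that("tutoring faster than the depression time scale skips units", {
  p <- rate_params(15)
  W0 <- random_weights(15, seed = 77)
  proto <- suppressWarnings(
    make_training_protocol("pulses", 15, cycle_length = 15 * 4, cycles = 20,
                           pulse_width = 4, probe = FALSE, tau_y = 20,
                           seed = 3))
  run <- train_network(W0, proto, plasticity_params(), p)
  link <- max(0.2, learned_link_strength(run$W, proto$schedule$order))
  sim <- simulate_rate_network(p, run$W, protocol_tonic(15, 0.5 * link),
                               duration = 400)
  expect_lt(length(unique(sim$trace$order)), 15)
})

test_that("weight perturbation has the stated statistics", {
  fx <- trained_15()
  W <- fx$run$W
  expect_identical(perturb_weights(W, 0, seed = 1), W)
  expect_identical(perturb_weights(W, 0.1, seed = 5),
                   perturb_weights(W, 0.1, seed = 5))
  mw <- mean(W[row(W) != col(W)])
  # Monte-Carlo: sd of the applied perturbation ~ p * |mean(W)| (measured on
  # interior entries, away from the clipping boundaries)
  deltas <- unlist(lapply(1:40, function(s) {
    Wp <- perturb_weights(W, 0.05, seed = 1000 + s)
    d <- (Wp - W)[row(W) != col(W) & W > -0.85 & W < -0.15]
    d
  }))
  expect_equal(sd(deltas), 0.05 * abs(mw), tolerance = 0.1)
  expect_true(all(perturb_weights(W, 0.5, seed = 2) >= -1))
  expect_true(all(perturb_weights(W, 0.5, seed = 2) <= 0))
})
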