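test_that("an isolated unit converges to the sigmoid of its input", {
  p <- rate_params(3, lam = 20)
  W <- matrix(0, 3, 3)
  st <- rate_state(rep(0.5, 3), rep(1, 3))
  for (k in 1:2000) st <- step_rate_network(st, W, rep(0.2, 3), 0.05, p)
  expect_equal(st$x, rep(sigmoid_transfer(0.2, 20), 3), tolerance = 1e-6)
  expect_equal(sigmoid_transfer(0.2, 20), 0.982, tolerance = 1e-3)
})

test_that("depression relaxes with the stated closed forms", {
  p <- rate_params(2, tau_y = 20, beta = 0.2)
  # x held at 0: y -> 1 with time constant tau_y
  y <- 0.5
  for (k in 1:1000) y <- y + (0.02 / 20) * (-(y - 1) * 1 - (y - 0.2) * 0)
  t_el <- 1000 * 0.02
  expect_equal(y, 1 - (1 - 0.5) * exp(-t_el / 20), tolerance = 2e-3)
  # x held at 1: y = beta + (y0 - beta) exp(-t / tau_y)
  y <- 1
  for (k in 1:1000) y <- y + (0.02 / 20) * (-(y - 0.2) * 1)
  expect_equal(y, 0.2 + 0.8 * exp(-t_el / 20), tolerance = 2e-3)
})

test_that("integration step enforces its contracts", {
  p <- rate_params(4)
  W <- build_sequence_weights(4, eta = 0.1)
  st <- one_hot_state(4)
  expect_error(step_rate_network(st, W, rep(0.5, 4), 0.5, p), "dt")
  expect_error(step_rate_network(st, W, rep(-0.1, 4), 0.02, p),
               "non-negative")
  Wpos <- W; Wpos[1, 2] <- 0.2
  expect_error(simulate_rate_network(p, Wpos, protocol_tonic(4, 0.5),
                                     duration = 10), "positive")
  expect_error(simulate_rate_network(p, W, protocol_tonic(4, 0.5),
                                     duration = 10, dt = 0.2), "dt")
  expect_error(simulate_rate_network(p, W, protocol_tonic(5, 0.5),
                                     duration = 10), "disagree")
})

test_that("activity and depression stay in their physical ranges", {
  p <- rate_params(10)
  W <- build_sequence_weights(10, eta = 0.1)
  sim <- simulate_rate_network(p, W, protocol_tonic(10, 0.54), duration = 200)
  late <- sim$t > 0                      # the one-hot start sits on the boundary
  expect_true(all(sim$x[late, ] > 0 & sim$x[late, ] < 1))
  expect_true(all(sim$y >= p$beta - 1e-9 & sim$y <= 1 + 1e-9))
})

test_that("without depression the winner-take-all state never switches", {
  # tau_y -> infinity keeps y pinned at 1: the initial winner holds
  p <- rate_params(10, tau_y = 1e9)
  W <- build_sequence_weights(10, eta = 0.1)
  sim <- simulate_rate_network(p, W, protocol_tonic(10, 0.54), duration = 150)
  expect_equal(unique(sim$trace$order), 1L)
  expect_gt(min(sim$y), 1 - 1e-4)
})

test_that("tonic drive expresses the wired order at a theory-led speed", {
  p <- rate_params(10)
  W <- build_sequence_weights(10, eta = 0.1)
  sim <- simulate_rate_network(p, W, protocol_tonic(10, 0.6 * 0.9),
                               duration = 160)
  expect_true(follows_cycle(sim$trace, 1:10))
  mt <- measure_switch_times(sim$trace)$mean
  expect_equal(mt, switch_time_theory(0.6, 0.2, 20), tolerance = 0.10)
})

test_that("strong pulsed input enslaves the network to the imposed order", {
  p <- rate_params(10)
  W <- build_sequence_weights(10, eta = 0.1)   # wired order 1..10
  shuf <- c(3, 7, 1, 9, 5, 2, 10, 6, 4, 8)
  pr <- protocol_pulses(10, order = shuf, cycle_length = 300, cycles = 2,
                        amplitude = 1.5)
  sim <- simulate_rate_network(p, W, pr)
  got <- sim$trace$order
  if (got[1] == 1 && shuf[1] != 1) got <- got[-1]   # initial one-hot unit
  expect_equal(got[seq_along(shuf)], shuf)
})

test_that("the input spotlight selects which stored path is expressed", {
  p <- rate_params(10)
  W <- build_multi_path_weights(10, list(c(1, 2, 3, 4), c(5, 6, 3, 7)),
                                eta = 0.2)
  mask <- rep(FALSE, 10); mask[c(5, 6, 3, 7)] <- TRUE
  sim <- simulate_rate_network(p, W, protocol_tonic(10, 0.4, mask = mask),
                               duration = 250, init_unit = 5)
  ord <- sim$trace$order
  expect_equal(ord[1:4], c(5, 6, 3, 7))
  expect_true(all(mask[ord]))                  # nothing outside the spotlight
})

test_that("sequence extraction is stable under time-step refinement", {
  p <- rate_params(8)
  W <- build_sequence_weights(8, eta = 0.1)
  pr <- protocol_tonic(8, 0.5 * 0.9)
  s1 <- simulate_rate_network(p, W, pr, duration = 150, dt = 0.02)
  s2 <- simulate_rate_network(p, W, pr, duration = 150, dt = 0.01)
  expect_equal(s1$trace$order, s2$trace$order)
  m1 <- measure_switch_times(s1$trace)$mean
  m2 <- measure_switch_times(s2$trace)$mean
  expect_equal(m1, m2, tolerance = 0.02)
})
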