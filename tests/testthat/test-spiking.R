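test_that("EIF rheobase follows from the printed constants", {
  sp <- spiking_params()
  expect_equal(eif_rheobase(sp), 0.54)
  expect_equal(spiking_params()$C / spiking_params()$g_L, 10)  # tau_m, ms
  sp_lif <- spiking_params(Delta_T = 1e-9)
  expect_equal(eif_rheobase(sp_lif), 0.6, tolerance = 1e-6)
  expect_error(spiking_params(u = 1.2), "u")
  expect_error(spiking_params(V_peak = -60), "V_peak")
})

test_that("clustered network construction is seeded Bernoulli without autapses", {
  net <- build_clustered_network(8, 100, 0.2, seed = 3)
  expect_equal(net$n, 800)
  expect_equal(tabulate(net$membership), rep(100, 8))
  expect_false(any(diag(net$conn)))
  n_syn <- sum(net$conn)
  mu <- 0.2 * 800 * 799
  expect_lt(abs(n_syn - mu), 3 * sqrt(mu * 0.8))
  expect_true(all(net$W[net$conn] >= -0.9 & net$W[net$conn] <= -0.5))
  expect_identical(build_clustered_network(8, 100, 0.2, seed = 3)$W, net$W)

  tiny <- build_clustered_network(2, 1, 1, seed = 1)
  expect_equal(unname(tiny$conn), matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  expect_error(build_clustered_network(2, 2, 0), "p_connect")
})

test_that("sin^8 tutoring current matches the printed waveform", {
  pars <- sin8_params(sd_x0 = 0, sd_x1 = 0, sd_theta = 0, sd_hf = 0)
  inp <- make_sin8_input(pars, 8, duration = 800, dt_in = 0.1)
  # cluster k peaks at x0 + x1 when sin^8(. ) = 1
  expect_equal(max(inp$input), 0.7, tolerance = 1e-4)
  # at the zero of its phase argument the current is the baseline x0
  k <- 8                                      # theta_8 = pi: sin(pi t/T + pi) = 0 at t = 0
  expect_equal(inp$input[1, k], 0.2, tolerance = 1e-6)
  expect_true(all(inp$input >= 0))
  # larger cluster index peaks one eighth of a cycle earlier (cyclically)
  t_peak <- inp$times[apply(inp$input[inp$times < 800, ], 2, which.max)]
  gaps <- (t_peak[-8] - t_peak[-1]) %% 800
  expect_true(all(abs(gaps - 100) < 2))
  # noise is redrawn per cycle but reproducible under the seed
  noisy <- sin8_params(seed = 9)
  a <- make_sin8_input(noisy, 8, 1600, 1)
  b <- make_sin8_input(noisy, 8, 1600, 1)
  expect_identical(a$input, b$input)
  c1 <- a$input[a$times < 800, 1]
  c2 <- a$input[a$times >= 800 & a$times < 1600, 1]
  expect_false(isTRUE(all.equal(c1, c2)))
})

test_that("STDP rule: pre-locked potentiation and coincidence depotentiation", {
  sd <- stdp_params()
  expect_equal(stdp_update(-0.5, numeric(), c(10, 20), sd), -0.5)
  expect_equal(stdp_update(-0.5, 50, numeric(), sd), -0.5 - 0.002)
  expect_equal(stdp_update(-0.5, 50, 50, sd), -0.5 - 0.002 + 0.05)
  # post shortly after pre: depotentiation through the pre trace
  w_seq <- stdp_update(-0.5, 50, 55, sd)
  expect_equal(w_seq, -0.5 - 0.002 + 0.05 * exp(-5 / 20))
  # post long before pre: only the constant potentiation remains
  w_far <- stdp_update(-0.5, 200, 100, sd)
  expect_equal(w_far, -0.502, tolerance = 1e-6)
  expect_true(stdp_update(-0.001, 50, 50, sd) <= 0)  # clipped at 0
  expect_error(stdp_params(A = 0.001, a = 0.002), "A")
})

test_that("membrane dynamics: silence without input, firing above rheobase", {
  net <- build_clustered_network(1, 2, 1, seed = 1)
  net$conn[] <- FALSE
  net$W[] <- 0
  sp <- spiking_params()
  expect_equal(nrow(simulate_spiking(net, 0, 500, sp)$raster), 0)
  expect_equal(nrow(simulate_spiking(net, 0.53, 1500, sp, V0 = "rest")$raster), 0)
  expect_gt(nrow(simulate_spiking(net, 0.56, 1500, sp, V0 = "rest")$raster), 2)
  s <- simulate_spiking(net, 0, 500, sp)
  expect_equal(s$V, rep(sp$E_L, 2), tolerance = 1e-4)
})

test_that("synaptic depression follows the release-recovery recursion", {
  # presynaptic neuron 1 driven; replay its spike train through the exact
  # recursion x <- (1-u) x at spikes, recovery exp(-dt/tau_x) between
  net <- build_clustered_network(2, 1, 1, seed = 1)
  net$W[] <- -0.5 * net$conn
  sp <- spiking_params()
  sim <- simulate_spiking(net, c(0.8, 0), 3000, sp, V0 = "rest")
  st <- sim$raster$time[sim$raster$neuron == 1]
  expect_gt(length(st), 20)
  x <- 1; t_prev <- 0; x_before <- NA
  for (tk in st) {
    x <- 1 - (1 - x) * exp(-(tk - t_prev) / sp$tau_x)
    x_before <- x
    x <- (1 - sp$u) * x
    t_prev <- tk
  }
  x_end <- 1 - (1 - x) * exp(-(3000 - t_prev) / sp$tau_x)
  # tolerance covers the release-vs-recovery ordering within one Euler step
  expect_equal(sim$x_syn[1], x_end, tolerance = 5e-3)
  # pre-spike value approaches the classical depressing-synapse fixed point
  isi <- mean(diff(utils::tail(st, 10)))
  x_star <- (1 - exp(-isi / sp$tau_x)) /
    (1 - (1 - sp$u) * exp(-isi / sp$tau_x))
  expect_equal(x_before, x_star, tolerance = 0.05)
  expect_true(all(sim$x_syn > 0 & sim$x_syn <= 1))
})

test_that("inhibition from a driven presynaptic neuron suppresses its target", {
  net <- build_clustered_network(2, 1, 1, seed = 1)
  net$W[] <- -1 * net$conn
  sp <- spiking_params(Q = 30)   # strong synapse for a 2-neuron motif
  both <- simulate_spiking(net, c(0.8, 0.6), 2000, sp, V0 = "rest")
  alone <- {
    net0 <- net; net0$conn[] <- FALSE; net0$W[] <- 0
    simulate_spiking(net0, c(0.8, 0.6), 2000, sp, V0 = "rest")
  }
  n2_with <- sum(both$raster$neuron == 2)
  n2_alone <- sum(alone$raster$neuron == 2)
  expect_lt(n2_with, n2_alone)
})
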