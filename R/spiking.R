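#' Exponential integrate-and-fire neuron and synapse parameters
#'
#' Single-neuron and synapse constants for the clustered spiking network.
#' Defaults: C = 300 pF, g_L = 30 nS, E_L = -70 mV, V_T = -50 mV,
#' Delta_T = 2 mV, tau_x = 200 ms, u = 0.5, Q = 1.5 pC.  A spike is recorded
#' when the membrane potential reaches `V_peak` (0 mV by default: at
#' dt = 0.05 ms the exponential term carries the potential from 0 mV to
#' divergence within a fraction of a step, so this is the numerical stand-in
#' for the divergence criterion) and the potential is reset to `E_L`.
#'
#' @param C Membrane capacitance, pF.
#' @param g_L Leak conductance, nS.
#' @param E_L Resting potential, mV.
#' @param V_T Exponential threshold, mV.
#' @param Delta_T Slope factor, mV.
#' @param tau_x Depression recovery time constant, ms.
#' @param u Release fraction per spike, in `[0, 1]`.
#' @param Q Synaptic charge scale, pC.
#' @param V_peak Spike-detection voltage, mV (> V_T).
#' @param dt Integration step, ms (<= 0.05).
#' @return An object of class `spiking_params`.
#' @export
spiking_params <- function(C = 300, g_L = 30, E_L = -70, V_T = -50,
                           Delta_T = 2, tau_x = 200, u = 0.5, Q = 1.5,
                           V_peak = 0, dt = 0.05) {
  if (C <= 0 || g_L <= 0 || Delta_T <= 0 || tau_x <= 0 || Q <= 0)
    stop("`C`, `g_L`, `Delta_T`, `tau_x`, `Q` must all be positive")
  if (u < 0 || u > 1) stop("`u` must be in [0, 1]")
  if (V_peak <= V_T) stop("`V_peak` must exceed `V_T`")
  if (dt <= 0 || dt > 0.05) stop("`dt` must be in (0, 0.05] ms")
  structure(list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
                 tau_x = tau_x, u = u, Q = Q, V_peak = V_peak, dt = dt),
            class = "spiking_params")
}

#' Rheobase current of the EIF neuron
#'
#' The minimum constant current for repetitive firing,
#' `g_L (V_T - E_L - Delta_T)`, in nA.  With the default constants this is
#' 30 nS x 18 mV = 0.54 nA.
#'
#' @param params A [spiking_params()].
#' @return Current in nA.
#' @export
eif_rheobase <- function(params) {
  stopifnot(inherits(params, "spiking_params"))
  params$g_L * (params$V_T - params$E_L - params$Delta_T) / 1000
}

#' Anti-Hebbian STDP parameters
#'
#' Trace-based spike-timing-dependent plasticity on the signed inhibitory
#' weights (entries in `[-1, 0]`).  Every presynaptic spike moves its
#' synapse by `-a` (potentiation toward -1) plus `A` times the postsynaptic
#' trace (depotentiation toward 0 for post-before-pre pairings within
#' `tau_post`); every postsynaptic spike adds `A` times the presynaptic
#' trace (depotentiation for post-after-pre pairings within `tau_pre`).
#' There is no weight change for synapses whose presynaptic neuron never
#' fires.  Defaults: A = 0.05, a = 0.002, tau_pre = 20 ms, tau_post = 5 ms.
#'
#' @param A Depotentiation amplitude (> a).
#' @param a Potentiation amplitude per presynaptic spike.
#' @param tau_pre Presynaptic trace time constant, ms.
#' @param tau_post Postsynaptic trace time constant, ms.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A = 0.05, a = 0.002, tau_pre = 20, tau_post = 5) {
  if (A <= 0 || a <= 0 || tau_pre <= 0 || tau_post <= 0)
    stop("all STDP parameters must be positive")
  if (A <= a) stop("`A` must exceed `a` (depotentiation dominates for correlated firing)")
  structure(list(A = A, a = a, tau_pre = tau_pre, tau_post = tau_post),
            class = "stdp_params")
}

#' Apply the STDP rule to one synapse given spike trains
#'
#' Reference implementation of the trace rule for a single synapse, useful
#' for inspecting the learning-rule kernel: given presynaptic and
#' postsynaptic spike times it returns the updated weight.  The network
#' simulator applies the identical rule to every synapse.
#'
#' @param w Initial weight in `[-1, 0]`.
#' @param pre_times,post_times Spike times in ms.
#' @param stdp A [stdp_params()].
#' @return Updated weight in `[-1, 0]`.
#' @export
stdp_update <- function(w, pre_times, post_times, stdp) {
  stopifnot(inherits(stdp, "stdp_params"))
  if (w < -1 || w > 0) stop("`w` must be in [-1, 0]")
  events <- rbind(
    if (length(pre_times)) data.frame(t = pre_times, pre = TRUE),
    if (length(post_times)) data.frame(t = post_times, pre = FALSE))
  if (is.null(events) || nrow(events) == 0) return(w)
  events <- events[order(events$t, !events$pre), ]   # pre processed first on ties
  pre_tr <- 0; post_tr <- 0; t_last <- -Inf
  clip <- function(v) min(0, max(-1, v))
  for (k in seq_len(nrow(events))) {
    dt_ev <- events$t[k] - t_last
    if (is.finite(dt_ev)) {
      pre_tr <- pre_tr * exp(-dt_ev / stdp$tau_pre)
      post_tr <- post_tr * exp(-dt_ev / stdp$tau_post)
    }
    t_last <- events$t[k]
    if (events$pre[k]) {
      w <- clip(w - stdp$a + stdp$A * post_tr)
      pre_tr <- pre_tr + 1
    } else {
      w <- clip(w + stdp$A * pre_tr)
      post_tr <- post_tr + 1
    }
  }
  w
}

#' Build a clustered spiking network
#'
#' `n_clusters` clusters of `cluster_size` EIF neurons with seeded Bernoulli
#' connectivity (probability `p_connect`, no autapses) and initial weights
#' drawn uniformly from `w_init_range` (a subset of `[-1, 0]`, so all
#' recurrent synapses are inhibitory with no initial sequence structure).
#'
#' @param n_clusters Number of clusters.
#' @param cluster_size Neurons per cluster.
#' @param p_connect Connection probability in (0, 1].
#' @param w_init_range Length-2 range within `[-1, 0]`.
#' @param seed Integer seed for connectivity and weights.
#' @return Object of class `spiking_network`: `n`, `membership`, `conn`
#'   (logical), `W`.
#' @export
build_clustered_network <- function(n_clusters = 8, cluster_size = 100,
                                    p_connect = 0.2,
                                    w_init_range = c(-0.9, -0.5), seed = 1) {
  if (p_connect <= 0 || p_connect > 1) stop("`p_connect` must be in (0, 1]")
  if (n_clusters < 1 || cluster_size < 1) stop("invalid network size")
  if (length(w_init_range) != 2L || any(w_init_range < -1) || any(w_init_range > 0))
    stop("`w_init_range` must be two numbers within [-1, 0]")
  n <- n_clusters * cluster_size
  built <- with_seed(seed, {
    conn <- matrix(runif(n * n) < p_connect, n)
    diag(conn) <- FALSE
    W <- matrix(0, n, n)
    W[conn] <- runif(sum(conn), min(w_init_range), max(w_init_range))
    list(conn = conn, W = W)
  })
  structure(list(n = n, n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 membership = rep(seq_len(n_clusters), each = cluster_size),
                 conn = built$conn, W = built$W, seed = seed),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("spiking network: %d clusters x %d neurons, %d synapses\n",
              x$n_clusters, x$cluster_size, sum(x$conn)))
  invisible(x)
}

#' Parameters of the sin^8 tutoring current
#'
#' Each neuron in cluster n receives
#' `I(t) = x0 + x1 * sin^8(pi t / period + theta_n)` with
#' `theta_n = pi n / n_clusters`, so the clusters' current bumps tile the
#' cycle and drive them in a fixed cyclic order (descending in cluster
#' index, since a larger phase offset makes the bump peak earlier).
#' Normally distributed noise, redrawn independently each cycle, perturbs
#' `x0`, `x1` and the phases, and higher-frequency terms
#' `sin(8 pi t / period)` and `sin(12 pi t / period)` with random amplitudes
#' and phases are added; the current is clipped at 0.
#'
#' Defaults: x0 = 0.2 nA, x1 = 0.5 nA, period = 800 ms; noise scales
#' sd_x0 = 0.02 nA, sd_x1 = 0.05 nA, sd_theta = 0.05 rad, sd_hf = 0.05 nA.
#'
#' @param x0 Baseline current, nA.
#' @param x1 Bump amplitude, nA.
#' @param period Input cycle length T, ms.
#' @param sd_x0,sd_x1,sd_theta,sd_hf Per-cycle noise scales (set all to 0
#'   for a noiseless tutor).
#' @param seed Integer seed for the per-cycle draws.
#' @return An object of class `sin8_params`.
#' @export
sin8_params <- function(x0 = 0.2, x1 = 0.5, period = 800, sd_x0 = 0.02,
                        sd_x1 = 0.05, sd_theta = 0.05, sd_hf = 0.05,
                        seed = 1) {
  if (period <= 0) stop("`period` must be positive")
  if (x0 < 0 || x1 < 0) stop("`x0` and `x1` must be non-negative")
  structure(list(x0 = x0, x1 = x1, period = period, sd_x0 = sd_x0,
                 sd_x1 = sd_x1, sd_theta = sd_theta, sd_hf = sd_hf,
                 seed = seed),
            class = "sin8_params")
}

#' Evaluate the sin^8 tutoring current per cluster
#'
#' Returns the per-cluster current matrix on a regular time grid, with the
#' per-cycle noise draws taken under the protocol seed.
#'
#' @param params A [sin8_params()].
#' @param n_clusters Number of clusters.
#' @param duration Total duration, ms.
#' @param dt_in Sampling interval of the returned grid, ms.
#' @return List: `input` (matrix, time samples x clusters), `times` (ms),
#'   `dt` (= `dt_in`).
#' @export
make_sin8_input <- function(params, n_clusters, duration, dt_in = 0.5) {
  stopifnot(inherits(params, "sin8_params"))
  times <- seq(0, duration, by = dt_in)
  n_cycles <- ceiling(duration / params$period)
  noise <- with_seed(params$seed, list(
    dx0 = rnorm(n_cycles, 0, params$sd_x0),
    dx1 = rnorm(n_cycles, 0, params$sd_x1),
    dth = matrix(rnorm(n_cycles * n_clusters, 0, params$sd_theta), n_cycles),
    a8 = abs(rnorm(n_cycles, 0, params$sd_hf)),
    p8 = runif(n_cycles, 0, 2 * pi),
    a12 = abs(rnorm(n_cycles, 0, params$sd_hf)),
    p12 = runif(n_cycles, 0, 2 * pi)))
  cyc <- pmin(floor(times / params$period) + 1, n_cycles)
  inp <- matrix(0, length(times), n_clusters)
  for (k in seq_len(n_clusters)) {
    theta <- pi * k / n_clusters + noise$dth[cbind(cyc, k)]
    inp[, k] <- (params$x0 + noise$dx0[cyc]) +
      (params$x1 + noise$dx1[cyc]) * sin(pi * times / params$period + theta)^8 +
      noise$a8[cyc] * sin(8 * pi * times / params$period + noise$p8[cyc]) +
      noise$a12[cyc] * sin(12 * pi * times / params$period + noise$p12[cyc])
  }
  inp[inp < 0] <- 0
  list(input = inp, times = times, dt = dt_in)
}

#' Simulate the clustered spiking network
#'
#' Euler integration (step `params$dt`) of the EIF membrane equation with
#' delta-synapse delivery: each presynaptic spike deposits the charge
#' `u * Q * x_syn * W` on its targets as an instantaneous voltage jump, then
#' depresses its synapses' transmitter pool by the factor `1 - u`; between
#' spikes the pool recovers toward 1 with `tau_x`.  With `stdp` supplied the
#' anti-Hebbian rule of [stdp_params()] runs online.
#'
#' @param network A [build_clustered_network()].
#' @param input Either a single tonic current (nA, applied to every
#'   cluster), a vector of per-cluster currents, or the list returned by
#'   [make_sin8_input()].
#' @param duration Simulated time, ms.
#' @param params A [spiking_params()].
#' @param stdp A [stdp_params()], or `NULL` for frozen weights.
#' @param V0 Initial membrane potentials: a numeric vector, or `"uniform"`
#'   (default) for potentials spread evenly across `[E_L, V_T]`, which keeps
#'   identically driven neurons desynchronized, or `"rest"` for all at
#'   `E_L`.
#' @return Object of class `spiking_sim`: `raster` (data frame `time`,
#'   `neuron`, `cluster`), `W` (final weights), `x_syn` (final per-neuron
#'   depression), `trace` (cluster [sequence_from_spikes()]), `network`.
#' @export
simulate_spiking <- function(network, input, duration,
                             params = spiking_params(), stdp = NULL,
                             V0 = "uniform") {
  stopifnot(inherits(network, "spiking_network"),
            inherits(params, "spiking_params"))
  if (is.numeric(input)) {
    lv <- if (length(input) == 1) rep(input, network$n_clusters) else input
    if (length(lv) != network$n_clusters)
      stop("tonic `input` must have length 1 or n_clusters")
    input <- list(input = matrix(lv, 1, network$n_clusters, byrow = TRUE),
                  dt = duration)
  }
  if (identical(V0, "uniform"))
    V0 <- params$E_L + (params$V_T - params$E_L) *
      (seq_len(network$n) - 1) / network$n
  else if (identical(V0, "rest")) V0 <- rep(params$E_L, network$n)
  if (length(V0) != network$n) stop("`V0` must have one entry per neuron")
  n_steps <- ceiling(duration / params$dt)
  res <- spiking_sim_cpp(network$W, network$conn, network$membership,
                         input$input, input$dt, params$dt, n_steps,
                         params$C, params$g_L, params$E_L, params$V_T,
                         params$Delta_T, params$V_peak, params$tau_x,
                         params$u, params$Q,
                         !is.null(stdp),
                         if (is.null(stdp)) 0 else stdp$A,
                         if (is.null(stdp)) 0 else stdp$a,
                         if (is.null(stdp)) 1 else stdp$tau_pre,
                         if (is.null(stdp)) 1 else stdp$tau_post,
                         V0)
  raster <- data.frame(time = res$spike_t, neuron = res$spike_id,
                       cluster = network$membership[res$spike_id])
  trace <- if (nrow(raster) > 0)
    sequence_from_spikes(raster, network$membership, t_max = duration)
  else structure(list(events = data.frame(onset = numeric(), unit = integer(),
                                          dwell = numeric()),
                      order = integer(), switch_times = numeric()),
                 class = "sequence_trace")
  structure(list(raster = raster, W = res$W, x_syn = res$x_syn, V = res$V,
                 trace = trace, network = network, params = params,
                 duration = duration),
            class = "spiking_sim")
}

#' @export
print.spiking_sim <- function(x, ...) {
  cat(sprintf("spiking simulation: %d neurons, %g ms, %d spikes, cluster order %s\n",
              x$network$n, x$duration, nrow(x$raster),
              paste(utils::head(x$trace$order, 10), collapse = " ")))
  invisible(x)
}

#' Train a spiking network with the sin^8 tutor and STDP
#'
#' Runs [simulate_spiking()] with STDP enabled under the noisy sin^8
#' tutoring current for `cycles` input cycles, then returns the trained
#' network together with the taught cluster order (the cyclic order imposed
#' by the tutor).
#'
#' @param network A [build_clustered_network()].
#' @param cycles Number of tutoring cycles.
#' @param input_params A [sin8_params()].
#' @param params A [spiking_params()].
#' @param stdp A [stdp_params()].
#' @return Object of class `spiking_training`: the trained `network` (with
#'   updated `W`), the training `sim`, and `taught_order`.
#' @export
train_spiking_network <- function(network, cycles = 40,
                                  input_params = sin8_params(),
                                  params = spiking_params(),
                                  stdp = stdp_params()) {
  duration <- cycles * input_params$period
  tutor <- make_sin8_input(input_params, network$n_clusters, duration)
  sim <- simulate_spiking(network, tutor, duration, params, stdp)
  trained <- network
  trained$W <- sim$W
  # taught order: phase offsets pi*n/n_clusters put larger cluster ids
  # earlier in the cycle, so the tutored order descends cyclically
  taught <- rev(seq_len(network$n_clusters))
  structure(list(network = trained, sim = sim, taught_order = taught,
                 input_params = input_params),
            class = "spiking_training")
}

#' Tonic-drive scan of the trained spiking network
#'
#' Drives the network with constant current (same to every neuron) at each
#' level, extracts the cluster sequence, and reports the mean cluster
#' switch time and whether the taught cyclic order was reproduced.
#'
#' @param network A trained [build_clustered_network()].
#' @param levels Tonic current levels, nA.
#' @param taught_order Cyclic cluster order to validate against.
#' @param duration Simulated time per level, ms.
#' @param params A [spiking_params()].
#' @param bin,min_rate Sequence-extraction settings
#'   ([sequence_from_spikes()]).
#' @param t_skip Initial window (ms) excluded as transient.
#' @return Data frame: `level`, `mean_T` (ms), `n_events`, `order_ok`.
#' @export
spiking_tonic_scan <- function(network, levels, taught_order,
                               duration = 6000, params = spiking_params(),
                               bin = 25, min_rate = 4, t_skip = 1500) {
  rows <- lapply(levels, function(lv) {
    sim <- simulate_spiking(network, lv, duration, params, stdp = NULL)
    tr <- trace_window(sequence_from_spikes(sim$raster, network$membership,
                                            bin = bin, min_rate = min_rate,
                                            t_max = duration),
                       t_skip, duration)
    mt <- if (nrow(tr$events) >= 3) measure_switch_times(tr)$mean else NA_real_
    data.frame(level = lv, mean_T = mt, n_events = nrow(tr$events),
               order_ok = follows_cycle(tr, taught_order, skip = 1,
                                        min_transitions = 3))
  })
  do.call(rbind, rows)
}
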