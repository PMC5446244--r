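#' One step of the presynaptic low-pass trace
#'
#' First-order exponential filter of the activities over the time scale
#' `tau_w`: `x_bar + dt / tau_w * (x - x_bar)`.  The trace is what makes the
#' learning rule sensitive to units active "together or immediately before"
#' the postsynaptic unit.
#'
#' @param x_bar Current trace vector.
#' @param x Activity vector.
#' @param dt Time step, > 0.
#' @param tau_w Trace time constant (units of tau).
#' @return Updated trace vector.
#' @export
lowpass_update <- function(x_bar, x, dt, tau_w) {
  if (dt <= 0) stop("`dt` must be positive")
  x_bar + dt / tau_w * (x - x_bar)
}

#' One Euler step of the anti-Hebbian weight dynamics
#'
#' Advances every weight by
#' \deqn{dW_{ij}/dt = -\alpha_1 W_{ij} x_i \bar{x}_j
#'       - \alpha_2 (W_{ij} + 1)(1 - x_i) \bar{x}_j.}
#' The first term drives the weight toward 0 (depotentiation) when the
#' postsynaptic unit fires together with or right after the presynaptic
#' unit; the second drives it back toward -1 (full inhibition) when the
#' presynaptic unit was recently active but the postsynaptic one is not.
#' The flow vanishes outward at both ends of `[-1, 0]`, so weights stay in
#' range; a numerical clip guards the Euler overshoot.
#'
#' @param W Weight matrix with entries in `[-1, 0]`.
#' @param x Activity vector.
#' @param x_bar Low-pass trace vector (see [lowpass_update()]).
#' @param dt Time step.
#' @param params A [plasticity_params()].
#' @return Updated weight matrix.
#' @export
weight_update <- function(W, x, x_bar, dt, params) {
  stopifnot(inherits(params, "plasticity_params"))
  validate_weights(W)
  dW <- -params$alpha1 * W * outer(x, x_bar) -
    params$alpha2 * (W + 1) * outer(1 - x, x_bar)
  W <- W + dt * dW
  W[W > 0] <- 0
  W[W < -1] <- -1
  W
}

#' Train a network on a tutoring protocol
#'
#' Co-integrates the rate dynamics, the presynaptic low-pass trace and the
#' anti-Hebbian weight dynamics while the network is driven by a tutoring
#' protocol (see [make_training_protocol()]).  The time-varying drive
#' enslaves the activity to the taught order; the plasticity depotentiates
#' each active unit's self-link and its link onto the next unit, carving
#' the sequence into the inhibitory connectivity so that afterwards plain
#' tonic input replays it.  Plasticity is frozen inside probe segments, so
#' the probes measure expression, not learning.  Calling `train_network()`
#' again on the returned weights with a new protocol overwrites the stored
#' sequence.
#'
#' @param W0 Initial weight matrix (e.g. [random_weights()]).
#' @param protocol Tutoring [input_protocol].
#' @param params A [plasticity_params()].
#' @param net_params A [rate_params()].
#' @param dt Integration step (default 0.02 tau).
#' @param snapshot_times Times at which to snapshot the weights.
#' @param record_dt Sampling interval of the stored activity trace.
#' @param input_dt Protocol sampling interval.
#' @return An object of class `training_run`: `W` (final weights),
#'   `snapshots` (list of weight matrices with `snapshot_times`), `t`, `x`,
#'   `trace`, `taught_order` (cyclic order realized during the final
#'   training cycle), and `probe_before` / `probe_after` sequence traces
#'   when the protocol carries probe segments.
#' @export
train_network <- function(W0, protocol, params, net_params, dt = 0.02,
                          snapshot_times = NULL, record_dt = 0.1,
                          input_dt = 0.1) {
  stopifnot(inherits(params, "plasticity_params"),
            inherits(net_params, "rate_params"),
            inherits(protocol, "input_protocol"))
  validate_weights(W0, net_params$n_units)
  if (protocol$n_units != net_params$n_units)
    stop("protocol and network disagree on the number of units")
  duration <- protocol$duration
  if (!is.finite(duration)) stop("training protocol must have finite duration")

  n_steps <- ceiling(duration / dt)
  in_times <- seq(0, n_steps * dt, by = input_dt)
  inp <- protocol_input(protocol, in_times)
  plastic <- !protocol_in_probe(protocol, in_times)
  snap_steps <- sort(unique(pmin(pmax(round(snapshot_times / dt), 1L), n_steps)))
  record_every <- max(1L, round(record_dt / dt))

  init <- one_hot_state(net_params$n_units, 1)
  res <- train_sim_cpp(W0, init$x, init$y, inp, input_dt, plastic,
                       dt, n_steps, net_params$beta, net_params$tau_y,
                       net_params$lam, params$alpha1, params$alpha2,
                       params$tau_w,
                       as.integer(snap_steps), record_every)
  trace <- active_unit_trace(res$x, res$t)

  # taught order: the cyclic order realized in the last plasticity-on cycle
  sch <- protocol$schedule
  taught <- NULL
  if (!is.null(sch$cycle_length)) {
    last_on <- if (is.null(protocol$probe)) duration
               else (sch$cycles - 0.5) * sch$cycle_length
    w <- trace_window(trace, last_on - sch$cycle_length, last_on)
    taught <- sequence_order(w)
  }

  probes <- list(before = NULL, after = NULL)
  if (!is.null(protocol$probe)) {
    segs <- protocol$probe
    probes$before <- trace_window(trace, segs[[1]][1], segs[[1]][2])
    probes$after <- trace_window(trace, segs[[2]][1], segs[[2]][2])
  }

  structure(list(W = res$W, W0 = W0,
                 snapshots = lapply(res$snapshots, identity),
                 snapshot_times = snap_steps * dt,
                 t = res$t, x = res$x, trace = trace,
                 taught_order = taught,
                 probe_before = probes$before, probe_after = probes$after,
                 protocol = protocol, params = params,
                 net_params = net_params),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("training run: %d units, %g tau, taught order %s\n",
              x$net_params$n_units, max(x$t),
              paste(x$taught_order, collapse = " ")))
  invisible(x)
}

#' Randomly perturb a weight matrix
#'
#' Adds `p * xi_ij * mean(W)` to every weight, with `xi_ij` independent
#' standard normal deviates and `mean(W)` the average over off-diagonal
#' entries; the result is clipped back to `[-1, 0]`.  Used to test how
#' robust a learned sequence is to synaptic noise.
#'
#' @param W Weight matrix.
#' @param p Perturbation fraction, >= 0.
#' @param seed Optional integer seed.
#' @return Perturbed weight matrix.
#' @export
perturb_weights <- function(W, p, seed = NULL) {
  validate_weights(W)
  if (p < 0) stop("`p` must be non-negative")
  n <- nrow(W)
  mw <- mean(W[row(W) != col(W)])
  draw <- function() matrix(rnorm(n * n), n)
  xi <- if (is.null(seed)) draw() else with_seed(seed, draw())
  W2 <- W + p * xi * mw
  W2[W2 > 0] <- 0
  W2[W2 < -1] <- -1
  W2
}

#' Mean magnitude of learned successor links
#'
#' For a learned matrix and a taught cyclic order, returns the mean absolute
#' weight of the successor links, i.e. the learned `1 - eta` of the stored
#' sequence.  Used to place tonic probe levels: the effective input of a
#' probe at level `xin` is `xin / link`, so scanning
#' `xin = x_hat * learned_link_strength(W, order)` probes effective inputs
#' `x_hat`.
#'
#' @param W Learned weight matrix.
#' @param order Cyclic taught order.
#' @return Mean of `|W[successor, unit]|` along the cycle.
#' @export
learned_link_strength <- function(W, order) {
  succ <- order[c(seq_along(order)[-1], 1)]
  mean(abs(W[cbind(succ, order)]))
}
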