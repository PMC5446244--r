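#' Instantaneous state of the rate network
#'
#' @param x Unit activities in (0, 1).
#' @param y Depression factors in `[beta, 1]`.
#' @param t Elapsed time (units of tau).
#' @return An object of class `rate_state`.
#' @export
rate_state <- function(x, y, t = 0) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  structure(list(x = as.numeric(x), y = as.numeric(y), t = t),
            class = "rate_state")
}

#' One-hot initial state
#'
#' The default initial condition: unit `k` fully active (x = 1), all other
#' units at 0.01, depression fully recovered (y = 1).
#'
#' @param n_units Number of units.
#' @param k Initially active unit (default 1).
#' @export
one_hot_state <- function(n_units, k = 1) {
  x <- rep(0.01, n_units)
  x[k] <- 1
  rate_state(x, rep(1, n_units))
}

#' Single explicit Euler step of the rate network
#'
#' Advances activities and depression variables by one step `dt`:
#' the drive on unit i is `sum_j W[i, j] x[j] y[j] + input_vec[i]` passed
#' through [sigmoid_transfer()], and each depression variable relaxes toward
#' 1 while its unit is silent and toward `beta` while it is active.  The
#' step must satisfy `dt <= 0.1 tau` (stability contract for the explicit
#' integrator); [simulate_rate_network()] runs the same scheme in compiled
#' code.
#'
#' @param state A [rate_state()].
#' @param W Weight matrix (entries in `[-1, 0]`).
#' @param input_vec Non-negative external drive per unit.
#' @param dt Time step, in `(0, 0.1 tau]`.
#' @param params A [rate_params()].
#' @return The updated `rate_state`.
#' @export
step_rate_network <- function(state, W, input_vec, dt, params) {
  stopifnot(inherits(state, "rate_state"), inherits(params, "rate_params"))
  if (dt <= 0 || dt > 0.1 * params$tau)
    stop("`dt` must be in (0, 0.1 tau] for the explicit integrator")
  if (any(input_vec < 0)) stop("external input must be non-negative")
  validate_weights(W, params$n_units)
  x <- state$x; y <- state$y
  drive <- as.numeric(W %*% (x * y)) + input_vec
  x_new <- x + dt * (-x + sigmoid_transfer(drive, params$lam))
  y_new <- y + (dt / params$tau_y) *
    (-(y - 1) * (1 - x) - (y - params$beta) * x)
  rate_state(x_new, y_new, state$t + dt)
}

#' Simulate the depressing winner-take-all rate network
#'
#' Integrates the rate model under an [input_protocol] with explicit Euler
#' in compiled code.  Under tonic drive the network expresses the sequence
#' wired into `W`, at a speed set by the input level; under strongly
#' time-dependent drive the activity is enslaved to the input.
#'
#' @param params A [rate_params()].
#' @param W Weight matrix, entries in `[-1, 0]`.
#' @param protocol An [input_protocol].
#' @param duration Simulated time (units of tau); defaults to the protocol
#'   duration when finite.
#' @param dt Integration step (default 0.02 tau; must be <= 0.1 tau).
#' @param init Initial state: a [rate_state()] or `"one_hot"`.
#' @param init_unit Active unit of the one-hot preset.
#' @param record_dt Sampling interval of the returned trajectory.
#' @param input_dt Sampling interval at which the protocol is evaluated and
#'   held piecewise constant.
#' @param threshold Activity threshold used to label the active unit.
#' @return An object of class `rate_sim`: list with `t`, matrices `x`, `y`
#'   (time samples x units), the `trace` ([active_unit_trace()]) and the
#'   call ingredients.
#' @examples
#' p <- rate_params(10)
#' W <- build_sequence_weights(10, eta = 0.1)
#' sim <- simulate_rate_network(p, W, protocol_tonic(10, 0.54), duration = 150)
#' sequence_order(sim$trace)
#' @export
simulate_rate_network <- function(params, W, protocol, duration = NULL,
                                  dt = 0.02, init = "one_hot", init_unit = 1,
                                  record_dt = 0.05, input_dt = 0.1,
                                  threshold = 0.5) {
  stopifnot(inherits(params, "rate_params"), inherits(protocol, "input_protocol"))
  validate_weights(W, params$n_units)
  if (protocol$n_units != params$n_units)
    stop("protocol and network disagree on the number of units")
  if (is.null(duration)) duration <- protocol$duration
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive and finite")
  if (dt <= 0 || dt > 0.1 * params$tau)
    stop("`dt` must be in (0, 0.1 tau] for the explicit integrator")

  state <- if (identical(init, "one_hot")) one_hot_state(params$n_units, init_unit)
           else init
  stopifnot(inherits(state, "rate_state"))

  n_steps <- ceiling(duration / dt)
  in_times <- seq(0, n_steps * dt, by = input_dt)
  inp <- protocol_input(protocol, in_times)
  record_every <- max(1L, round(record_dt / dt))

  res <- rate_sim_cpp(W, state$x, state$y, inp, input_dt, dt, n_steps,
                      params$beta, params$tau_y, params$lam, record_every)
  out <- list(t = res$t, x = res$x, y = res$y,
              trace = active_unit_trace(res$x, res$t, threshold = threshold),
              params = params, W = W, protocol = protocol, dt = dt)
  class(out) <- "rate_sim"
  out
}

#' @export
print.rate_sim <- function(x, ...) {
  cat(sprintf("rate simulation: %d units, %g tau, %d events (order %s)\n",
              x$params$n_units, max(x$t), nrow(x$trace$events),
              paste(utils::head(x$trace$order, 12), collapse = " ")))
  invisible(x)
}

#' Tonic-probe scan of switch times
#'
#' Runs the network under tonic drive at several input levels and measures
#' the mean switch time at each, together with the closed-form prediction
#' and whether the realized order followed `reference` (a cyclic unit
#' order).  The probe duration at each level is adapted to the predicted
#' switch time so that several hand-offs are observed even at the slowest
#' speeds.
#'
#' @param params A [rate_params()].
#' @param W Weight matrix.
#' @param xin Vector of tonic input levels (raw, not effective).
#' @param eta Link depotentiation used to convert `xin` to the effective
#'   input for the theory column (default estimated per link is not
#'   attempted here; pass the known value).
#' @param reference Cyclic unit order the realized sequence should follow
#'   (default `1:n_units`).
#' @param n_switches Number of hand-offs to aim for at each level.
#' @param mask Optional spotlight mask applied at every level.
#' @param ... Passed to [simulate_rate_network()].
#' @return Data frame: `xin`, `x_hat_in`, `mean_T` (measured), `theory_T`,
#'   `n_events`, `order_ok`.
#' @export
scan_switch_times <- function(params, W, xin, eta, reference = seq_len(params$n_units),
                              n_switches = 6, mask = NULL, ...) {
  x_hat <- effective_input(xin, eta)
  rows <- lapply(seq_along(xin), function(k) {
    theory <- if (x_hat[k] > params$beta && x_hat[k] <= 1)
      switch_time_theory(x_hat[k], params$beta, params$tau_y) else NA_real_
    dur <- if (is.finite(theory)) (n_switches + 2) * theory + 20 else 400
    sim <- simulate_rate_network(params, W,
                                 protocol_tonic(params$n_units, xin[k], mask = mask),
                                 duration = dur, ...)
    tr <- sim$trace
    mt <- if (nrow(tr$events) >= 3) measure_switch_times(tr)$mean else NA_real_
    data.frame(xin = xin[k], x_hat_in = x_hat[k], mean_T = mt,
               theory_T = theory, n_events = nrow(tr$events),
               order_ok = follows_cycle(tr, reference))
  })
  do.call(rbind, rows)
}
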