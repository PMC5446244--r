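#' Parameters of the excitatory network with shared inhibition
#'
#' N excitatory units with self- and feedforward excitation `J` (entries at
#' least 0) project onto one shared inhibitory unit (weight `J_IE`) which
#' inhibits them all back (weight `J_EI`).  The excitatory synapses are
#' depressing: every occurrence of a presynaptic activity on the right-hand
#' side is multiplied by that unit's depression factor.  With fast linear
#' inhibition the model reduces exactly to the recurrent inhibitory network
#' with effective weights `J - J_EI * J_IE` (see
#' [effective_inhibitory_weights()]).
#'
#' Defaults follow the standard operating point: `J_EI = J_IE = 1`,
#' `tau_I = tau`, `J = 0.6 I + 0.2` on the subdiagonal, beta = 0.2,
#' tau_y = 20, lam = 20.
#'
#' @param J Excitatory weight matrix (entries >= 0), or `NULL` to build it
#'   from `n_units`, `j_self`, `j_ff`.
#' @param n_units Number of excitatory units (used when `J` is `NULL`).
#' @param j_self Self-excitation (diagonal of the default `J`).
#' @param j_ff Feedforward excitation (subdiagonal of the default `J`).
#' @param cyclic Wrap the feedforward link from the last unit to the first.
#' @param J_EI,J_IE Inhibitory loop weights, >= 0.
#' @param tau_I Inhibitory time constant (units of tau).
#' @param phi_I Inhibitory transfer function: `"rectified_tanh"` (default)
#'   or `"linear"`.
#' @param beta,tau_y,lam As in [rate_params()].
#' @return An object of class `ei_params`.
#' @export
ei_params <- function(J = NULL, n_units = 10, j_self = 0.6, j_ff = 0.2,
                      cyclic = TRUE, J_EI = 1, J_IE = 1, tau_I = 1,
                      phi_I = c("rectified_tanh", "linear"),
                      beta = 0.2, tau_y = 20, lam = 20) {
  phi_I <- match.arg(phi_I)
  if (is.null(J)) {
    J <- diag(j_self, n_units)
    for (j in seq_len(n_units - 1)) J[j + 1, j] <- j_ff
    if (cyclic) J[1, n_units] <- j_ff
  }
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("`J` must be square")
  if (any(J < 0)) stop("`J` entries must be non-negative (excitatory)")
  if (J_EI < 0 || J_IE < 0) stop("`J_EI` and `J_IE` must be non-negative")
  if (tau_I <= 0) stop("`tau_I` must be positive")
  check_beta(beta)
  if (J_EI * J_IE < max(J))
    warning("J_EI * J_IE < max(J): the mapping onto the effective inhibitory model is invalid")
  structure(list(J = J, n_units = nrow(J), J_EI = J_EI, J_IE = J_IE,
                 tau_I = tau_I, phi_I = phi_I, beta = beta, tau_y = tau_y,
                 lam = lam),
            class = "ei_params")
}

#' @export
print.ei_params <- function(x, ...) {
  cat(sprintf("E-I network: %d excitatory units + shared inhibition, J_I = %g, tau_I = %g tau, phi_I = %s\n",
              x$n_units, x$J_EI * x$J_IE, x$tau_I, x$phi_I))
  invisible(x)
}

#' Simulate the excitatory network with shared inhibition
#'
#' Integrates
#' \deqn{\tau   \dot{x}_i = -x_i + \phi(\sum_j J_{ij} x_j y_j - J_{EI} x_I + x^{in}_i)}
#' \deqn{\tau_I \dot{x}_I = -x_I + \phi_I(J_{IE} \sum_j x_j y_j)}
#' with the depression dynamics of [rate_params()] attached to each
#' excitatory unit.  With moderate tonic input the network produces sparse
#' sequential activation along the feedforward links, with the input level
#' controlling the speed; the finite inhibitory time constant caps how fast
#' switching can get, so the achievable dynamic range is narrower than in
#' the purely inhibitory network.
#'
#' @param params An [ei_params()].
#' @param protocol An [input_protocol].
#' @param duration Simulated time (units of tau).
#' @param dt Integration step (default 0.02).
#' @param init Initial state: `"one_hot"` or a list with `x`, `x_I`, `y`.
#' @param record_dt,input_dt,threshold As in [simulate_rate_network()].
#' @return Object of class `ei_sim`: `t`, `x`, `y`, `x_I`, `trace`.
#' @export
simulate_ei_network <- function(params, protocol, duration = NULL, dt = 0.02,
                                init = "one_hot", record_dt = 0.05,
                                input_dt = 0.1, threshold = 0.5) {
  stopifnot(inherits(params, "ei_params"), inherits(protocol, "input_protocol"))
  if (protocol$n_units != params$n_units)
    stop("protocol and network disagree on the number of units")
  if (is.null(duration)) duration <- protocol$duration
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be positive and finite")
  if (dt <= 0 || dt > 0.1) stop("`dt` must be in (0, 0.1 tau]")

  if (identical(init, "one_hot")) {
    s <- one_hot_state(params$n_units, 1)
    init <- list(x = s$x, x_I = 0, y = s$y)
  }
  n_steps <- ceiling(duration / dt)
  in_times <- seq(0, n_steps * dt, by = input_dt)
  inp <- protocol_input(protocol, in_times)
  record_every <- max(1L, round(record_dt / dt))

  res <- ei_sim_cpp(params$J, params$J_EI, params$J_IE,
                    init$x, init$x_I, init$y, inp, input_dt, dt, n_steps,
                    params$beta, params$tau_y, params$lam, params$tau_I,
                    params$phi_I == "linear", record_every)
  structure(list(t = res$t, x = res$x, y = res$y, x_I = res$x_I,
                 trace = active_unit_trace(res$x, res$t, threshold = threshold),
                 params = params, protocol = protocol),
            class = "ei_sim")
}

#' Effective inhibitory weights of the E-I network
#'
#' In the limit of fast linear inhibition the shared inhibitory unit tracks
#' `J_IE * sum_j x_j y_j` instantaneously, so each unit effectively receives
#' `sum_j (J_ij - J_I) x_j y_j` with `J_I = J_EI * J_IE`.  When
#' `J_I >= max(J)` the effective matrix `W = J - J_I` is non-positive and the
#' model is exactly the recurrent inhibitory network.
#'
#' @param params An [ei_params()].
#' @return Non-positive weight matrix usable with [simulate_rate_network()].
#' @export
effective_inhibitory_weights <- function(params) {
  stopifnot(inherits(params, "ei_params"))
  J_I <- params$J_EI * params$J_IE
  if (J_I < max(params$J))
    stop("J_EI * J_IE must be >= every entry of J for the reduction to hold")
  params$J - J_I
}

#' Bracket the stable-sequence input range of the E-I network
#'
#' The E-I network expresses its feedforward sequence only over a window of
#' tonic input: below it the shared inhibition extinguishes the hand-off
#' (the sequence dies rather than slows), above it activity loses
#' winner-take-all sparseness.  This locates both edges by bisection
#' between a failing and a working level, then returns a scan across the
#' bracketed range, from which the achievable dynamic range of sequence
#' periods is measured.
#'
#' @param params An [ei_params()].
#' @param lo,hi Levels assumed below / above the stable window.
#' @param probe An initial working level inside the window.
#' @param tol Bisection tolerance on the input level.
#' @param n_levels Number of scan levels across the bracket.
#' @param ... Passed to [scan_ei_periods()].
#' @return List with `lower`, `upper` (bracket edges) and `scan` (the
#'   data frame of [scan_ei_periods()] across the bracket).
#' @export
bracket_ei_range <- function(params, lo = 0.1, hi = 1.2, probe = 0.6,
                             tol = 0.005, n_levels = 10, ...) {
  works <- function(lv) {
    tab <- scan_ei_periods(params, lv, ...)
    isTRUE(tab$order_ok[1]) && is.finite(tab$mean_T[1])
  }
  if (!works(probe)) stop("`probe` level does not produce a stable sequence")
  bisect <- function(bad, good) {
    while (abs(good - bad) > tol) {
      mid <- (bad + good) / 2
      if (works(mid)) good <- mid else bad <- mid
    }
    good
  }
  lower <- bisect(lo, probe)
  upper <- bisect(hi, probe)
  levels <- seq(lower, upper, length.out = n_levels)
  list(lower = lower, upper = upper,
       scan = scan_ei_periods(params, levels, ...))
}

#' Tonic-input scan of the E-I network's sequence period
#'
#' Simulates the network at each tonic level, extracts the cluster sequence,
#' and records the mean switch time and whether the realized order followed
#' the feedforward cycle.  Used to bracket the stable-sequence regime and
#' measure the achievable dynamic range.
#'
#' @param params An [ei_params()].
#' @param levels Tonic input levels.
#' @param duration Simulation length per level (default adapts upward for
#'   slow levels).
#' @param reference Cyclic reference order (default `1:n_units`).
#' @param ... Passed to [simulate_ei_network()].
#' @return Data frame: `level`, `mean_T`, `n_events`, `order_ok`.
#' @export
scan_ei_periods <- function(params, levels, duration = 600,
                            reference = seq_len(params$n_units), ...) {
  rows <- lapply(levels, function(lv) {
    sim <- simulate_ei_network(params,
                               protocol_tonic(params$n_units, lv),
                               duration = duration, ...)
    # analyse the second half only: the hand-off pattern needs a few laps
    # to settle from the one-hot initial condition
    tr <- trace_window(sim$trace, duration / 2, duration)
    mt <- if (nrow(tr$events) >= 3) measure_switch_times(tr)$mean else NA_real_
    data.frame(level = lv, mean_T = mt, n_events = nrow(tr$events),
               order_ok = follows_cycle(tr, reference, skip = 0,
                                        min_transitions = 3))
  })
  do.call(rbind, rows)
}
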