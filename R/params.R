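#' Rate-network parameters
#'
#' Parameters of the depressing winner-take-all rate network.  Times are in
#' units of the membrane time constant tau (fixed at 1): `tau_y` is the
#' depression recovery time constant, `beta` the floor the depression
#' variable reaches while a unit stays active, and `lam` the sigmoid gain.
#' Defaults are the standard operating point (beta = 0.2, tau_y = 20 tau,
#' lam = 20), at which the network produces clean winner-take-all sequences.
#'
#' @param n_units Number of units (clusters of MSNs), >= 2.
#' @param tau_y Depression recovery time constant (units of tau), > 0.
#' @param beta Minimum depression factor, in `[0, 1)`.
#' @param lam Sigmoid gain, > 0.
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(10)
#' @export
rate_params <- function(n_units, tau_y = 20, beta = 0.2, lam = 20) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 2 ||
      n_units != round(n_units))
    stop("`n_units` must be a single integer >= 2")
  check_beta(beta)
  if (tau_y <= 0) stop("`tau_y` must be positive")
  if (lam <= 0) stop("`lam` must be positive")
  structure(list(n_units = as.integer(n_units), tau = 1, tau_y = tau_y,
                 beta = beta, lam = lam),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("rate network: %d units, tau_y = %g tau, beta = %g, lambda = %g\n",
              x$n_units, x$tau_y, x$beta, x$lam))
  invisible(x)
}

#' Anti-Hebbian plasticity parameters
#'
#' Learning rates of the anti-Hebbian weight dynamics and the time constant
#' of the presynaptic low-pass trace.  `alpha1` sets how fast synapses
#' between co-active or sequentially active units are depotentiated (driven
#' toward 0), `alpha2` how fast all other synapses from recently active
#' units are potentiated back toward the fully inhibitory value -1.  Defaults
#' are alpha1 = 0.05/tau, alpha2 = 0.02/tau, tau_w = 3 tau.
#'
#' The trace time constant `tau_w` should not exceed the typical dwell time
#' of a unit, otherwise links skipping ahead two or more steps in the
#' sequence are also depotentiated; a warning (not an error) is emitted when
#' `dwell_time` is supplied and exceeded.
#'
#' @param alpha1 Depotentiation rate (1/tau), > 0.
#' @param alpha2 Potentiation rate (1/tau), > 0.
#' @param tau_w Low-pass trace time constant (units of tau), > 0.
#' @param dwell_time Optional typical active dwell time used for the
#'   `tau_w` sanity warning.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha1 = 0.05, alpha2 = 0.02, tau_w = 3,
                              dwell_time = NULL) {
  if (alpha1 <= 0 || alpha2 <= 0 || tau_w <= 0)
    stop("`alpha1`, `alpha2` and `tau_w` must all be positive")
  if (!is.null(dwell_time) && tau_w > dwell_time)
    warning("`tau_w` exceeds the typical dwell time: synapses two or more steps ",
            "back in the sequence will also be depotentiated")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, tau_w = tau_w),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf("anti-Hebbian plasticity: alpha1 = %g/tau, alpha2 = %g/tau, tau_w = %g tau\n",
              x$alpha1, x$alpha2, x$tau_w))
  invisible(x)
}
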