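#' Sigmoidal transfer function
#'
#' The unit nonlinearity \eqn{\phi(v) = 1 / (1 + e^{-\lambda v})} used by the
#' rate models.  `lam` is the gain: large gains make units nearly binary.
#'
#' @param v Input drive (any real value; must be finite).
#' @param lam Gain \eqn{\lambda > 0}.
#' @return Activity in (0, 1), same length as `v`.
#' @examples
#' sigmoid_transfer(0, 20)    # 0.5
#' sigmoid_transfer(0.1, 20)  # ~0.881
#' @export
sigmoid_transfer <- function(v, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lam` must be a single positive finite number")
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("`v` must be finite numeric")
  1 / (1 + exp(-lam * v))
}

#' Effective tonic input of a depotentiated sequence link
#'
#' A link from unit j to its successor carries weight \eqn{-(1-\eta)}, so the
#' switch condition depends on the input only through
#' \eqn{\hat{x}^{in} = x^{in} / (1 - \eta)}.
#'
#' @param xin Tonic input level (>= 0).
#' @param eta Depotentiation of sequence links, in `[0, 1)`.
#' @return The effective input level.
#' @examples
#' effective_input(0.54, 0.1)  # 0.6
#' @export
effective_input <- function(xin, eta) {
  check_eta(eta)
  if (any(xin < 0)) stop("`xin` must be non-negative")
  xin / (1 - eta)
}

#' Closed-form switch time under tonic drive
#'
#' While a unit is active its outgoing depression variable decays as
#' \eqn{y(t) = \beta + (1-\beta) e^{-t/\tau_y}}; the successor takes over when
#' the depressed inhibition it receives falls to the level of its input,
#' \eqn{y(T) = \hat{x}^{in}}.  Solving gives
#' \deqn{T = \tau_y \log[(1-\beta) / (\hat{x}^{in} - \beta)].}
#' The switch time diverges as the effective input approaches the depression
#' floor \eqn{\beta}, which is what gives the model its wide dynamic range of
#' sequence speeds.
#'
#' @param x_hat_in Effective tonic input, in \eqn{(\beta, 1]}.  Vectorised.
#' @param beta Depression floor, in `[0, 1)`.
#' @param tau_y Depression recovery time constant (units of tau).
#' @return Switch time in units of tau.
#' @examples
#' switch_time_theory(0.6, beta = 0.2, tau_y = 20)  # 20 log(2) ~ 13.86
#' @export
switch_time_theory <- function(x_hat_in, beta, tau_y) {
  check_beta(beta)
  if (tau_y <= 0) stop("`tau_y` must be positive")
  if (any(x_hat_in <= beta))
    stop("`x_hat_in` must exceed `beta`: below the depression floor the switch time diverges")
  if (any(x_hat_in > 1)) stop("`x_hat_in` must be <= 1")
  tau_y * log((1 - beta) / (x_hat_in - beta))
}

#' Temporal scaling factor Tmax / Tmin for an input margin
#'
#' If the tonic input is confined to \eqn{[\beta + \Delta, 1 - \Delta]} (for
#' example because noise makes the boundaries unreliable), the achievable
#' switch times span the ratio
#' \deqn{T_{max}/T_{min} = \log[(1-\beta)/\Delta] \, / \,
#'       \log[(1-\beta)/(1-\beta-\Delta)].}
#'
#' @param beta Depression floor, in `[0, 1)`.
#' @param delta Input margin \eqn{\Delta} in \eqn{(0, (1-\beta)/2]}. Vectorised.
#' @return Ratio of slowest to fastest switch time (>= 1).
#' @examples
#' temporal_scaling_factor(0.2, 0.1)  # log(8)/log(8/7) ~ 15.6
#' @export
temporal_scaling_factor <- function(beta, delta) {
  check_beta(beta)
  if (any(delta <= 0 | delta > (1 - beta) / 2))
    stop("`delta` must lie in (0, (1 - beta)/2]")
  switch_time_theory(beta + delta, beta, 1) / switch_time_theory(1 - delta, beta, 1)
}

# shared argument checks
check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1)
    stop("`beta` must be a single number in [0, 1)")
  invisible(beta)
}
check_eta <- function(eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta >= 1)
    stop("`eta` must be a single number in [0, 1)")
  invisible(eta)
}
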