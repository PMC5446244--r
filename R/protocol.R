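#' Input protocols for the rate models
#'
#' An input protocol is a declarative description of the external excitatory
#' drive \eqn{x^{in}_i(t)} to every unit.  Protocols are deterministic
#' functions of time: any randomness (sinusoid amplitudes and phases) is
#' drawn once at construction under the protocol's seed, so the same
#' `(kind, schedule, seed)` always reproduces the same input.  Evaluate a
#' protocol on a time grid with [protocol_input()].
#'
#' * `protocol_tonic()`: constant drive `level`, optionally restricted by a
#'   logical `mask` (the "spotlight" that selects which stored sequence is
#'   expressed; unmasked units receive 0).
#' * `protocol_pulses()`: each cycle, the units in `order` receive one
#'   rectangular pulse of width `pulse_width` in turn, a strongly
#'   time-dependent drive that enslaves the network to the imposed order.
#' * `protocol_sinusoids()`: a smooth random tutor: each unit receives one
#'   raised-cosine-power bump per cycle (a trigonometric polynomial in the
#'   cycle frequency) at a seeded random time with a random amplitude, on
#'   top of a small tonic floor.
#' * `protocol_explicit()`: piecewise-constant drive from a user matrix.
#'
#' Any protocol may carry `probe` segments, time windows in which the drive
#' is replaced by a constant level to all units (used to probe what sequence
#' the network expresses on its own; plasticity is frozen there during
#' training).
#'
#' @param level Tonic amplitude (>= 0).
#' @param mask Optional logical vector selecting driven units.
#' @param n_units Number of units the protocol drives.
#' @param duration Total protocol duration (units of tau).
#' @name input_protocol
NULL

new_protocol <- function(kind, n_units, duration, level = 0, mask = NULL,
                         schedule = list(), probe = NULL, seed = NULL) {
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != n_units)
      stop("`mask` must be a logical vector of length n_units")
  }
  if (level < 0) stop("`level` must be non-negative")
  if (!is.null(probe)) {
    for (seg in probe)
      if (length(seg) != 3L || seg[1] < 0 || seg[2] <= seg[1] || seg[3] < 0)
        stop("each probe segment must be c(start, end, level) with 0 <= start < end and level >= 0")
  }
  structure(list(kind = kind, n_units = as.integer(n_units),
                 duration = duration, level = level, mask = mask,
                 schedule = schedule, probe = probe, seed = seed),
            class = "input_protocol")
}

#' @rdname input_protocol
#' @param probe Optional list of probe segments, each `c(start, end, level)`.
#' @export
protocol_tonic <- function(n_units, level, duration = Inf, mask = NULL,
                           probe = NULL) {
  new_protocol("tonic", n_units, duration, level = level, mask = mask,
               probe = probe)
}

#' @rdname input_protocol
#' @param order Integer vector: the unit order imposed by the pulses
#'   (default `1:n_units`).
#' @param cycle_length Duration of one input cycle (units of tau).
#' @param cycles Number of cycles.
#' @param pulse_width Width of each pulse; defaults to
#'   `cycle_length / length(order)` (contiguous pulses).
#' @param amplitude Pulse height.
#' @export
protocol_pulses <- function(n_units, order = seq_len(n_units), cycle_length,
                            cycles, pulse_width = cycle_length / length(order),
                            amplitude = 1.5, probe = NULL) {
  if (any(order < 1 | order > n_units)) stop("`order` contains invalid unit ids")
  if (cycle_length <= 0 || cycles < 1) stop("invalid cycle schedule")
  if (pulse_width <= 0 || pulse_width > cycle_length / length(order))
    stop("`pulse_width` must be in (0, cycle_length / length(order)]")
  new_protocol("pulses", n_units, cycles * cycle_length, level = amplitude,
               schedule = list(order = as.integer(order),
                               cycle_length = cycle_length,
                               cycles = as.integer(cycles),
                               pulse_width = pulse_width),
               probe = probe)
}

#' @rdname input_protocol
#' @param amp_range Range of the per-unit bump amplitudes.
#' @param floor Tonic floor added to every unit's drive.
#' @param width_frac Bump full width at half maximum, as a fraction of the
#'   cycle slot `cycle_length / n_units`.
#' @param jitter Uniform jitter of the bump times, in slots.
#' @param seed Integer seed for the amplitudes and bump times.
#' @export
protocol_sinusoids <- function(n_units, cycle_length, cycles,
                               amp_range = c(0.45, 0.65), floor = 0.05,
                               width_frac = 0.8, jitter = 0.15,
                               probe = NULL, seed = 1) {
  if (cycle_length <= 0 || cycles < 1) stop("invalid cycle schedule")
  # Smooth periodic tutor: each unit receives one raised-cosine-power bump
  # per cycle, cos^k(pi (t - t_i) / cycle), a trigonometric polynomial in
  # the cycle frequency.  Bump times are a seeded random permutation of the
  # cycle slots with jitter, so the taught order is a random simple cycle;
  # amplitudes are random.  The exponent k is set so the bump FWHM is
  # `width_frac` of a slot: the falling edge of the drive must release a
  # unit on the depression time scale, otherwise activity ping-pongs back
  # to the predecessor (whose input is still high) and no clean sequence
  # is taught -- the smooth analogue of requiring pulse widths >= tau_y.
  slot <- cycle_length / n_units
  u_half <- pi * (width_frac * slot / 2) / cycle_length
  k_exp <- 2 * max(1, round(log(2) / (-2 * log(cos(u_half)))))
  draws <- with_seed(seed, list(
    amp = runif(n_units, min(amp_range), max(amp_range)),
    t_peak = (sample(n_units) - 1 + runif(n_units, -jitter, jitter)) * slot))
  new_protocol("sinusoids", n_units, cycles * cycle_length,
               schedule = list(cycle_length = cycle_length,
                               cycles = as.integer(cycles),
                               amp = draws$amp, t_peak = draws$t_peak,
                               k_exp = k_exp, floor = floor),
               probe = probe, seed = seed)
}

#' @rdname input_protocol
#' @param times Sample times (strictly increasing, starting at 0) for
#'   `protocol_explicit`.
#' @param values Matrix `length(times)` x `n_units` of non-negative drives,
#'   held piecewise constant.
#' @export
protocol_explicit <- function(values, times, duration = max(times)) {
  if (!is.matrix(values) || nrow(values) != length(times))
    stop("`values` must be a matrix with one row per time")
  if (any(values < 0)) stop("inputs must be non-negative")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  new_protocol("explicit", ncol(values), duration,
               schedule = list(times = times, values = values))
}

#' Evaluate a protocol on a time grid
#'
#' @param protocol An [input_protocol] object.
#' @param times Numeric vector of times.
#' @return A `length(times)` x `n_units` non-negative matrix of drives.
#' @export
protocol_input <- function(protocol, times) {
  stopifnot(inherits(protocol, "input_protocol"))
  n <- protocol$n_units
  sch <- protocol$schedule
  inp <- switch(protocol$kind,
    tonic = {
      m <- matrix(protocol$level, length(times), n)
      if (!is.null(protocol$mask)) m[, !protocol$mask] <- 0
      m
    },
    pulses = {
      m <- matrix(0, length(times), n)
      tc <- times %% sch$cycle_length
      slot <- sch$cycle_length / length(sch$order)
      for (k in seq_along(sch$order)) {
        on <- tc >= (k - 1) * slot & tc < (k - 1) * slot + sch$pulse_width &
          times < protocol$duration
        m[on, sch$order[k]] <- protocol$level
      }
      m
    },
    sinusoids = {
      m <- matrix(sch$floor, length(times), n)
      for (i in seq_len(n))
        m[, i] <- m[, i] + sch$amp[i] *
          abs(cos(pi * (times - sch$t_peak[i]) / sch$cycle_length))^sch$k_exp
      m[m < 0] <- 0
      m[times >= protocol$duration, ] <- 0
      m
    },
    explicit = {
      idx <- pmin(findInterval(times, sch$times), length(sch$times))
      idx[idx < 1] <- 1
      sch$values[idx, , drop = FALSE]
    },
    stop("unknown protocol kind: ", protocol$kind))
  if (!is.null(protocol$probe)) {
    for (seg in protocol$probe) {
      sel <- times >= seg[1] & times < seg[2]
      inp[sel, ] <- seg[3]
    }
  }
  inp
}

#' Which protocol samples fall inside probe segments
#'
#' Used internally to freeze plasticity during probes.
#'
#' @inheritParams protocol_input
#' @return Logical vector along `times`; `TRUE` inside a probe segment.
#' @export
protocol_in_probe <- function(protocol, times) {
  out <- rep(FALSE, length(times))
  for (seg in protocol$probe) out[times >= seg[1] & times < seg[2]] <- TRUE
  out
}

#' @export
print.input_protocol <- function(x, ...) {
  cat(sprintf("input protocol '%s': %d units, duration %g tau%s\n",
              x$kind, x$n_units,
              x$duration,
              if (is.null(x$probe)) "" else sprintf(", %d probe segment(s)",
                                                    length(x$probe))))
  invisible(x)
}

#' Tutoring protocol for sequence training
#'
#' Convenience constructor for the training drives: either a regular
#' sequence of pulse-like inputs (one pulse per unit per cycle, in a fixed
#' order) or a seeded random superposition of sinusoids per unit.  With
#' `probe = TRUE` the first half of the first cycle and the last half of the
#' last cycle are replaced by constant input to all units, so the same run
#' yields the expressed sequence before and after training.
#'
#' Learning succeeds when the drive varies on time scales of at least the
#' depression recovery time tau_y; a pulse width well below tau_y makes the
#' network skip units (a warning is issued, since that failure mode is
#' sometimes the point).
#'
#' @param kind `"pulses"` or `"sinusoids"`.
#' @param n_units Number of units.
#' @param cycle_length Cycle duration (units of tau).
#' @param cycles Number of training cycles.
#' @param order Taught unit order (pulses only; default a seeded random
#'   permutation).
#' @param pulse_width Pulse width (pulses only; default one slot).
#' @param probe Logical; add the before/after tonic probe segments.
#' @param probe_level Tonic level used in the probe segments.
#' @param tau_y Depression time constant used only for the pulse-width
#'   warning.
#' @param seed Integer seed (random order and sinusoid draws).
#' @return An [input_protocol].
#' @export
make_training_protocol <- function(kind = c("pulses", "sinusoids"), n_units,
                                   cycle_length, cycles, order = NULL,
                                   pulse_width = NULL, probe = TRUE,
                                   probe_level = 0.2, tau_y = 20, seed = 1) {
  kind <- match.arg(kind)
  probe_segs <- if (probe) {
    list(c(0, cycle_length / 2, probe_level),
         c((cycles - 0.5) * cycle_length, cycles * cycle_length, probe_level))
  } else NULL
  if (kind == "pulses") {
    if (is.null(order)) order <- with_seed(seed, sample(n_units))
    if (is.null(pulse_width)) pulse_width <- cycle_length / length(order)
    if (pulse_width < tau_y)
      warning("pulse width below tau_y: units are likely to be skipped in the learned sequence")
    protocol_pulses(n_units, order = order, cycle_length = cycle_length,
                    cycles = cycles, pulse_width = pulse_width,
                    probe = probe_segs)
  } else {
    protocol_sinusoids(n_units, cycle_length = cycle_length, cycles = cycles,
                       probe = probe_segs, seed = seed)
  }
}
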