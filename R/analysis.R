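#' Extract the active-unit sequence from an activity trajectory
#'
#' At each sample the active unit is the argmax of the activities, reported
#' only when the maximum exceeds `threshold` (ties broken toward the lowest
#' index).  Runs of the same label are merged into events.  The result is a
#' `sequence_trace`: the time-stamped record of which unit (or cluster) held
#' the winner-take-all spotlight, from which switch times and periods are
#' measured.
#'
#' @param x Matrix of activities, time samples x units.
#' @param t Sample times (same length as `nrow(x)`).
#' @param threshold Activity threshold in (0, 1); default 0.5.
#' @return An object of class `sequence_trace`: list with `events`
#'   (data frame `onset`, `unit`, `dwell`), `order` (the realized unit id
#'   sequence) and `switch_times` (intervals between successive onsets).
#' @export
active_unit_trace <- function(x, t, threshold = 0.5) {
  if (!is.matrix(x) || nrow(x) == 0) stop("`x` must be a non-empty matrix")
  if (length(t) != nrow(x)) stop("`t` must match the rows of `x`")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  peak <- apply(x, 1, max)
  winner <- max.col(x, ties.method = "first")
  winner[peak <= threshold] <- NA_integer_
  new_sequence_trace(winner, t)
}

new_sequence_trace <- function(winner, t) {
  lab <- ifelse(is.na(winner), 0L, winner)
  change <- c(TRUE, diff(lab) != 0)
  starts <- which(change)
  ends <- c(starts[-1] - 1L, length(lab))
  keep <- lab[starts] != 0L
  onset <- t[starts][keep]
  unit <- lab[starts][keep]
  t_end <- vapply(which(keep), function(k) {
    if (ends[k] < length(t)) t[ends[k] + 1L] else t[length(t)]
  }, numeric(1))
  events <- data.frame(onset = onset, unit = unit, dwell = t_end - onset)
  structure(list(events = events, order = events$unit,
                 switch_times = diff(events$onset)),
            class = "sequence_trace")
}

#' @export
print.sequence_trace <- function(x, ...) {
  cat(sprintf("sequence trace: %d events, order %s%s\n", nrow(x$events),
              paste(utils::head(x$order, 15), collapse = " "),
              if (nrow(x$events) > 15) " ..." else ""))
  invisible(x)
}

#' Mean switch time of a sequence trace
#'
#' Intervals between successive event onsets; the first interval is treated
#' as transient and excluded from the mean.
#'
#' @param trace A `sequence_trace` with at least two events.
#' @return List with `mean` and the full `intervals` vector.
#' @export
measure_switch_times <- function(trace) {
  stopifnot(inherits(trace, "sequence_trace"))
  iv <- trace$switch_times
  if (length(iv) < 1) stop("need at least 2 events to measure switch times")
  m <- if (length(iv) >= 2) mean(iv[-1]) else iv
  list(mean = m, intervals = iv)
}

#' Restrict a trace to a time window
#'
#' @param trace A `sequence_trace`.
#' @param t0,t1 Window bounds; events with onset in `[t0, t1)` are kept.
#' @return A `sequence_trace`.
#' @export
trace_window <- function(trace, t0, t1) {
  ev <- trace$events[trace$events$onset >= t0 & trace$events$onset < t1, ,
                     drop = FALSE]
  structure(list(events = ev, order = ev$unit,
                 switch_times = diff(ev$onset)),
            class = "sequence_trace")
}

#' Does a realized sequence follow a cyclic reference order?
#'
#' Checks that every transition between consecutive events (after an
#' optional number of initial transient events) steps to the successor
#' defined by the cyclic order `cycle`, and that no unit outside `cycle`
#' ever appears.
#'
#' @param trace A `sequence_trace`.
#' @param cycle Integer vector giving the cyclic reference order.
#' @param skip Number of initial events to ignore as transient (default 1).
#' @param min_transitions Minimum number of checked transitions for a
#'   `TRUE` verdict.
#' @return Logical.
#' @export
follows_cycle <- function(trace, cycle, skip = 1, min_transitions = 2) {
  ord <- trace$order
  if (skip > 0 && length(ord) > skip) ord <- ord[-seq_len(skip)]
  if (length(ord) == 0 || !all(ord %in% cycle)) return(FALSE)
  if (length(ord) < min_transitions + 1) return(FALSE)
  succ <- cycle[c(seq_along(cycle)[-1], 1)]
  names(succ) <- as.character(cycle)
  all(succ[as.character(ord[-length(ord)])] == ord[-1])
}

#' Cyclic order realized by a trace
#'
#' Returns the repeating unit cycle expressed by the trace: the sequence of
#' units between successive visits to the most visited unit.  `NULL` when no
#' complete cycle is present.
#'
#' @param trace A `sequence_trace`.
#' @return Integer vector (one period of the cycle), or `NULL`.
#' @export
sequence_cycle <- function(trace) {
  ord <- trace$order
  if (length(ord) < 3) return(NULL)
  anchor <- as.integer(names(which.max(table(ord))))
  hits <- which(ord == anchor)
  if (length(hits) < 2) return(NULL)
  ord[hits[1]:(hits[2] - 1)]
}

#' Order of unique units in a trace
#'
#' The realized unit sequence with consecutive duplicates and repeats
#' removed: the first appearance order of each unit.
#'
#' @param trace A `sequence_trace`.
#' @return Integer vector of unit ids.
#' @export
sequence_order <- function(trace) {
  unique(trace$order)
}

#' Dynamic range of sequence speeds across input levels
#'
#' Given measured periods (or mean switch times) across tonic input levels,
#' returns max/min over the levels whose realized sequence was valid
#' (completed the reference order).
#'
#' @param period Numeric vector of measured periods.
#' @param valid Logical vector: did the level produce the reference
#'   sequence?  Default all valid.
#' @return The max/min period ratio.
#' @export
dynamic_range <- function(period, valid = rep(TRUE, length(period))) {
  ok <- valid & is.finite(period)
  if (sum(ok) < 2)
    stop("need at least two input levels with a valid sequence")
  max(period[ok]) / min(period[ok])
}

#' Score the sequence structure stored in a weight matrix
#'
#' After learning, each column of the weight matrix belonging to a
#' sequence-active unit should have a single depotentiated (least negative)
#' off-diagonal entry, at the row of that unit's successor.  The score is
#' the fraction of columns in `reference` whose off-diagonal argmax matches
#' the reference successor.  A column whose entries are all equal is
#' degenerate (the argmax falls on the lowest index by tie-breaking) and is
#' flagged.
#'
#' @param W Weight matrix.
#' @param reference Integer vector: the cyclic taught order.
#' @return List with `accuracy`, `successors` (named predicted successor per
#'   reference unit) and `degenerate` (logical per reference unit).
#' @export
weight_structure_score <- function(W, reference) {
  validate_weights(W)
  n <- nrow(W)
  if (any(reference < 1 | reference > n)) stop("`reference` names unknown units")
  if (anyDuplicated(reference)) stop("`reference` must not repeat units")
  succ_true <- reference[c(seq_along(reference)[-1], 1)]
  pred <- integer(length(reference))
  degen <- logical(length(reference))
  for (k in seq_along(reference)) {
    j <- reference[k]
    col <- W[, j]
    col[j] <- -Inf                       # off-diagonal argmax
    pred[k] <- which.max(col)
    degen[k] <- sum(col == max(col)) > 1
  }
  list(accuracy = mean(pred == succ_true),
       successors = setNames(pred, reference),
       degenerate = setNames(degen, reference))
}

#' Cluster-level sequence from a spike raster
#'
#' Bins the raster, computes each cluster's population firing rate per bin,
#' and labels each bin with the cluster of highest rate provided it exceeds
#' `min_rate` (Hz per neuron).  Consecutive identical labels are merged into
#' events as in [active_unit_trace()].
#'
#' @param raster Data frame with columns `time` (ms) and `neuron`.
#' @param membership Integer vector mapping neuron id to cluster.
#' @param bin Bin width in ms (default 20).
#' @param min_rate Minimum population rate (Hz per neuron) for a winner.
#' @param t_max End of the analysed window (default last spike time).
#' @return A `sequence_trace` (onsets in ms).
#' @export
sequence_from_spikes <- function(raster, membership, bin = 20, min_rate = 5,
                                 t_max = NULL) {
  if (bin <= 0) stop("`bin` must be positive")
  if (nrow(raster) == 0) stop("empty spike raster")
  n_clu <- max(membership)
  cl_size <- tabulate(membership, n_clu)
  if (is.null(t_max)) t_max <- max(raster$time)
  edges <- seq(0, t_max + bin, by = bin)
  n_bins <- length(edges) - 1
  counts <- matrix(0, n_bins, n_clu)
  bi <- findInterval(raster$time, edges, rightmost.closed = TRUE)
  cl <- membership[raster$neuron]
  for (k in seq_along(bi))
    if (bi[k] >= 1 && bi[k] <= n_bins) counts[bi[k], cl[k]] <- counts[bi[k], cl[k]] + 1
  rate <- sweep(counts, 2, cl_size, "/") / (bin / 1000)   # Hz per neuron
  peak <- apply(rate, 1, max)
  winner <- max.col(rate, ties.method = "first")
  winner[peak < min_rate] <- NA_integer_
  new_sequence_trace(winner, edges[-length(edges)])
}

#' Cluster-averaged weight matrix
#'
#' Entry (a, b) is the mean weight over existing synapses from cluster b
#' onto cluster a.  Pairs with no synapse are reported as `NA`.
#'
#' @param W Synaptic weight matrix (post x pre).
#' @param membership Integer vector mapping neuron id to cluster.
#' @param conn Logical synapse-existence matrix; default: every entry of
#'   `W` is a synapse (no autapses excluded).
#' @return A `n_clusters` x `n_clusters` matrix.
#' @export
cluster_average_weights <- function(W, membership, conn = NULL) {
  if (length(membership) != nrow(W)) stop("`membership` must cover all neurons")
  if (is.null(conn)) conn <- matrix(TRUE, nrow(W), ncol(W))
  n_clu <- max(membership)
  out <- matrix(NA_real_, n_clu, n_clu)
  for (a in seq_len(n_clu)) {
    ia <- membership == a
    for (b in seq_len(n_clu)) {
      jb <- membership == b
      sel <- conn[ia, jb, drop = FALSE]
      if (any(sel)) out[a, b] <- mean(W[ia, jb, drop = FALSE][sel])
    }
  }
  out
}
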