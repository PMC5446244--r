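#' Handcrafted sequence weight matrix
#'
#' Builds the fully connected inhibitory weight matrix in which all
#' off-diagonal entries are -1 except the links from unit j to unit j + 1,
#' which are depotentiated by `eta` (weight \eqn{-(1-\eta)}).  The unit with
#' the least inhibition from the currently active unit is its successor, so
#' this matrix stores the sequence 1, 2, ..., N.  With `cyclic = TRUE` the
#' link from the last unit back to the first is depotentiated as well, making
#' the sequence repeat.  Diagonal entries are 0.
#'
#' Convention: `W[i, j]` is the weight from presynaptic unit j onto
#' postsynaptic unit i, so the recurrent drive on unit i is
#' `sum_j W[i, j] * x[j] * y[j]`.
#'
#' @param n_units Number of units, >= 2.
#' @param eta Depotentiation of sequence links, in `[0, 1)`.
#' @param cyclic Depotentiate the wrap-around link (default `TRUE`).
#' @return An `n_units` x `n_units` matrix with entries in `[-1, 0]`.
#' @examples
#' build_sequence_weights(5, eta = 0.2)
#' @export
build_sequence_weights <- function(n_units, eta, cyclic = TRUE) {
  if (n_units < 2 || n_units != round(n_units))
    stop("`n_units` must be an integer >= 2")
  check_eta(eta)
  W <- matrix(-1, n_units, n_units)
  diag(W) <- 0
  for (j in seq_len(n_units - 1)) W[j + 1, j] <- -(1 - eta)
  if (cyclic) W[1, n_units] <- -(1 - eta)
  W
}

#' Weight matrix storing several (possibly overlapping) sequences
#'
#' Starts from the uniform inhibitory matrix (off-diagonal -1, diagonal 0)
#' and depotentiates the link for every consecutive pair along every path.
#' Links shared between paths are depotentiated once (idempotent), so
#' overlapping subsequences are recycled rather than duplicated.  Which path
#' is expressed at run time is chosen by the input "spotlight": restrict the
#' tonic drive to one path's units and only that sequence can unfold.
#'
#' @param n_units Number of units.
#' @param paths List of integer vectors, each a sequence of distinct unit
#'   indices in `1:n_units`.
#' @param eta Depotentiation applied to every path link, in `[0, 1)`.
#' @return Weight matrix with entries in `[-1, 0]`.
#' @examples
#' build_multi_path_weights(8, list(c(1, 2, 3, 4), c(5, 3, 4, 6)), eta = 0.1)
#' @export
build_multi_path_weights <- function(n_units, paths, eta) {
  if (n_units < 2 || n_units != round(n_units))
    stop("`n_units` must be an integer >= 2")
  check_eta(eta)
  if (!is.list(paths)) paths <- list(paths)
  W <- matrix(-1, n_units, n_units)
  diag(W) <- 0
  for (p in paths) {
    if (any(p < 1 | p > n_units | p != round(p)))
      stop("path contains an index outside 1:n_units")
    if (anyDuplicated(p)) stop("path indices must be distinct within a path")
    if (length(p) >= 2)
      for (k in seq_len(length(p) - 1)) W[p[k + 1], p[k]] <- -(1 - eta)
  }
  W
}

#' Random initial inhibitory connectivity
#'
#' Off-diagonal entries drawn uniformly from `range` (a subset of `[-1, 0]`),
#' diagonal 0; the unstructured starting point for sequence learning.
#'
#' @param n_units Number of units.
#' @param range Length-2 numeric range within `[-1, 0]`.
#' @param seed Optional integer seed.
#' @return Weight matrix.
#' @export
random_weights <- function(n_units, range = c(-1, -0.5), seed = NULL) {
  if (length(range) != 2L || any(range < -1) || any(range > 0))
    stop("`range` must be two numbers within [-1, 0]")
  draw <- function() {
    W <- matrix(runif(n_units * n_units, min(range), max(range)), n_units)
    diag(W) <- 0
    W
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Check a weight matrix for the inhibitory rate model
#'
#' @param W Matrix to validate.
#' @param n_units Optional expected side length.
#' @return `W`, invisibly; errors describe the violated contract.
#' @export
validate_weights <- function(W, n_units = NULL) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("`W` must be a square matrix")
  if (!is.null(n_units) && nrow(W) != n_units)
    stop(sprintf("`W` must be %d x %d", n_units, n_units))
  if (any(W > 0)) stop("`W` must have no positive entries (inhibitory network)")
  if (any(W < -1)) stop("`W` entries must be >= -1")
  invisible(W)
}
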