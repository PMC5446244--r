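test_that("active-unit extraction merges runs and applies the threshold", {
  t <- seq(0, 9, by = 1)
  x <- matrix(0.1, 10, 3)
  x[1:4, 2] <- 0.9
  x[5:8, 3] <- 0.8
  tr <- active_unit_trace(x, t)
  expect_s3_class(tr, "sequence_trace")
  expect_equal(tr$order, c(2, 3))
  expect_equal(tr$events$onset, c(0, 4))
  expect_equal(tr$events$dwell[1], 4)
  # single constant winner: one event for the whole duration
  xc <- matrix(0.05, 10, 3); xc[, 1] <- 0.95
  trc <- active_unit_trace(xc, t)
  expect_equal(nrow(trc$events), 1)
  expect_equal(trc$events$dwell, 9)
  # everything below threshold: no events
  expect_equal(nrow(active_unit_trace(matrix(0.2, 5, 3), 1:5)$events), 0)
  expect_error(active_unit_trace(matrix(0, 0, 3), numeric()), "non-empty")
  # ties go to the lowest index
  xt <- matrix(0.9, 2, 3)
  expect_equal(active_unit_trace(xt, 1:2)$order, 1)
})

test_that("switch-time measurement drops the transient interval", {
  tr <- structure(list(events = data.frame(onset = c(0, 12, 22, 32),
                                           unit = 1:4, dwell = 10),
                       order = 1:4, switch_times = c(12, 10, 10)),
                  class = "sequence_trace")
  m <- measure_switch_times(tr)
  expect_equal(m$mean, 10)
  expect_equal(m$intervals, c(12, 10, 10))
  one <- structure(list(events = data.frame(onset = 0, unit = 1, dwell = 1),
                        order = 1, switch_times = numeric()),
                   class = "sequence_trace")
  expect_error(measure_switch_times(one), "2 events")
})

test_that("cycle-following check handles rotations, breaks and repeats", {
  mk <- function(ord) structure(
    list(events = data.frame(onset = seq_along(ord), unit = ord, dwell = 1),
         order = ord, switch_times = rep(1, length(ord) - 1)),
    class = "sequence_trace")
  expect_true(follows_cycle(mk(c(3, 4, 5, 1, 2, 3, 4)), 1:5, skip = 0))
  expect_false(follows_cycle(mk(c(1, 2, 4, 5)), 1:5, skip = 0))
  expect_false(follows_cycle(mk(c(1, 2, 2, 3)), 1:5, skip = 0))
  expect_false(follows_cycle(mk(c(1, 2, 6)), 1:5, skip = 0))    # foreign unit
  expect_true(follows_cycle(mk(c(9, 1, 2, 3, 4)), 1:5, skip = 1))
  expect_false(follows_cycle(mk(c(1, 2)), 1:5, skip = 0))       # too short
})

test_that("dynamic range uses only levels with a valid sequence", {
  expect_equal(dynamic_range(c(20, 2)), 10)
  expect_equal(dynamic_range(c(40, 20, 2), valid = c(FALSE, TRUE, TRUE)), 10)
  expect_error(dynamic_range(c(5), valid = TRUE), "two")
  expect_error(dynamic_range(c(5, NA), valid = c(TRUE, TRUE)), "two")
})

test_that("weight structure score reads successors off the columns", {
  W <- build_sequence_weights(8, eta = 0.2)
  sc <- weight_structure_score(W, 1:8)
  expect_equal(sc$accuracy, 1)
  expect_equal(unname(sc$successors), c(2:8, 1))
  expect_false(any(sc$degenerate))
  # degenerate all-equal matrix: ties resolve to the lowest index
  Wd <- matrix(-1, 4, 4); diag(Wd) <- 0
  scd <- weight_structure_score(Wd, 1:4)
  expect_true(all(scd$degenerate))
  expect_equal(unname(scd$successors), c(2, 1, 1, 1))
  expect_equal(scd$accuracy, 0.5)   # j=1 and j=4 match by tie-breaking
  expect_error(weight_structure_score(W, c(1, 9)), "unknown")
  expect_error(weight_structure_score(W, c(1, 1, 2)), "repeat")
})

test_that("cluster sequences are recovered from spike rasters", {
  # synthetic raster: clusters 1..4 fire in 100 ms blocks, 5 neurons each
  membership <- rep(1:4, each = 5)
  mk_block <- function(cl, t0) data.frame(
    time = rep(seq(t0 + 1, t0 + 99, by = 4), each = 5),
    neuron = rep(which(membership == cl), times = 25))
  raster <- do.call(rbind, lapply(1:4, function(c) mk_block(c, (c - 1) * 100)))
  tr <- sequence_from_spikes(raster, membership, bin = 20, min_rate = 5)
  expect_equal(tr$order, 1:4)
  expect_true(max(abs(tr$events$onset - c(0, 100, 200, 300))) <= 20)
  # below the rate floor nothing is labelled
  sparse <- raster[seq(1, nrow(raster), by = 50), ]
  expect_equal(nrow(sequence_from_spikes(sparse, membership, bin = 20,
                                         min_rate = 50)$events), 0)
  expect_error(sequence_from_spikes(raster[0, ], membership), "empty")
})

test_that("cluster-averaged weights reduce and flag missing synapses", {
  membership <- rep(1:2, each = 2)
  W <- matrix(-0.5, 4, 4)
  cw <- cluster_average_weights(W, membership)
  expect_true(all(cw == -0.5))
  # per-neuron clusters with full connectivity reduce to W itself
  conn <- matrix(TRUE, 4, 4)
  expect_equal(cluster_average_weights(W, 1:4, conn), W)
  # no synapse between a pair: NA
  conn2 <- matrix(TRUE, 4, 4); conn2[3:4, 1:2] <- FALSE
  cw2 <- cluster_average_weights(W, membership, conn2)
  expect_true(is.na(cw2[2, 1]))
  expect_equal(cw2[1, 2], -0.5)
  expect_error(cluster_average_weights(W, 1:3), "cover")
})
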