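test_that("config validation names the offending field", {
  expect_error(experiment_config(list(experiment = "warp")), "experiment")
  err <- tryCatch(experiment_config(list(experiment = "rate",
                                         network = list(beta = 1.5))),
                  error = function(e) e)
  expect_s3_class(err, "striatseq_config_error")
  expect_match(conditionMessage(err), "network.beta")
  expect_error(experiment_config(list(experiment = "rate", dt = 0.5)), "dt")
  expect_error(experiment_config("/no/such/config.yaml"), "not found")
})

test_that("configs round-trip through YAML", {
  cfg <- list(experiment = "rate", seed = 7,
              network = list(n_units = 6, eta = 0.2),
              protocol = list(kind = "tonic", level = 0.5),
              duration = 80)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  loaded <- experiment_config(f)
  expect_equal(unclass(loaded)[names(cfg)], cfg)
})

test_that("a master seed makes experiments fully reproducible", {
  cfg <- list(experiment = "rate", seed = 3,
              network = list(n_units = 6, eta = 0.2),
              protocol = list(kind = "sinusoids", cycle_length = 120,
                              cycles = 1),
              duration = 120)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$events, r2$events)
  cfg$seed <- 4
  r3 <- run_experiment(cfg)
  expect_false(identical(r1$events, r3$events))
})

test_that("child seeds are deterministic, named and within integer range", {
  expect_identical(child_seed(42, "connectivity"), child_seed(42, "connectivity"))
  expect_false(child_seed(42, "connectivity") == child_seed(42, "protocol"))
  expect_false(child_seed(42, "protocol") == child_seed(43, "protocol"))
  s <- vapply(1:50, function(k) child_seed(k, "x"), integer(1))
  expect_true(all(s > 0 & s < 2^31))
})

test_that("artifact bundles round-trip and reject corruption", {
  cfg <- list(experiment = "rate", seed = 1,
              network = list(n_units = 6, eta = 0.2),
              protocol = list(kind = "tonic", level = 0.5), duration = 60)
  res <- run_experiment(cfg)
  res$table <- data.frame(level = c(0.3, 0.5), mean_T = c(30, 15))
  dir <- tempfile("bundle")
  save_bundle(res, dir, config = experiment_config(cfg))
  loaded <- load_bundle(dir)
  expect_equal(loaded$manifest$kind, "rate")
  expect_equal(loaded$events, res$events)
  expect_equal(loaded$scan, res$table)
  expect_equal(loaded$config$seed, 1)
  # truncated bundle: listed file missing
  file.remove(file.path(dir, "events.csv"))
  expect_error(load_bundle(dir), "truncated")
  expect_error(load_bundle(tempfile()), "manifest")
  # version stamp mismatch
  dir2 <- tempfile("bundle")
  save_bundle(res, dir2)
  mf <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  mf$version <- 99
  jsonlite::write_json(mf, file.path(dir2, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_bundle(dir2), "version")
})

test_that("weight round-trip through a bundle preserves values", {
  W <- build_sequence_weights(7, eta = 0.15)
  res <- list(kind = "train",
              run = list(W = W,
                         trace = structure(
                           list(events = data.frame(onset = 1, unit = 1,
                                                    dwell = 2),
                                order = 1, switch_times = numeric()),
                           class = "sequence_trace")))
  dir <- tempfile("wb")
  save_bundle(res, dir)
  loaded <- load_bundle(dir)
  expect_equal(loaded$weights, unname(W), tolerance = 1e-12)
})

test_that("the packaged example config runs end to end", {
  cfg <- system.file("extdata", "speed-scan.yaml", package = "striatseq")
  res <- run_experiment(cfg)
  expect_equal(res$kind, "scan")
  expect_true(all(res$table$order_ok))
  expect_true(all(diff(res$table$mean_T) < 0))
  expect_gt(res$dynamic_range, 1)
})
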