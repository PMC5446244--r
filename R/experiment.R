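#' Validate an experiment configuration
#'
#' An experiment config is a named list (typically read from YAML) with an
#' `experiment` selector (`"rate"`, `"train"`, `"ei"`, `"spiking"` or
#' `"scan"`), a master `seed`, and the parameter blocks of the selected
#' pipeline.  Validation errors name the offending field.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (class `experiment_config`).
#' @export
experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) cfg_stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) cfg_stop("config must be a named list or YAML path")
  if (is.null(config$experiment) ||
      !config$experiment %in% c("rate", "train", "ei", "spiking", "scan"))
    cfg_stop("experiment: must be one of rate, train, ei, spiking, scan")
  config$seed <- config$seed %||% 1L
  if (!is.numeric(config$seed)) cfg_stop("seed: must be an integer")
  net <- config$network %||% list()
  chk_num <- function(value, field, lo = -Inf, hi = Inf) {
    if (!is.null(value) && (!is.numeric(value) || value < lo || value >= hi))
      cfg_stop(sprintf("%s: must be a number in [%g, %g)", field, lo, hi))
  }
  chk_num(net$beta, "network.beta", 0, 1)
  chk_num(net$eta, "network.eta", 0, 1)
  chk_num(net$tau_y, "network.tau_y", 1e-12)
  chk_num(net$lam, "network.lam", 1e-12)
  chk_num(config$dt, "dt", 1e-12, 0.1000001)
  structure(config, class = c("experiment_config", "list"))
}

cfg_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("striatseq_config_error",
                                             "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment
#'
#' Executes the pipeline selected by `config$experiment` and returns its
#' result object; with `out_dir` set, also writes a plain-text artifact
#' bundle ([save_bundle()]).  Every stochastic component derives its stream
#' from the master seed via [child_seed()], so rerunning the same config
#' reproduces all outputs exactly.
#'
#' Pipelines:
#' * `rate`: simulate a handcrafted sequence network under its protocol.
#' * `scan`: tonic speed scan of a handcrafted network
#'   ([scan_switch_times()]).
#' * `train`: tutor a random network ([train_network()]), optionally
#'   perturb and probe.
#' * `ei`: tonic scan of the excitatory/shared-inhibition network.
#' * `spiking`: train the clustered spiking network and scan tonic drive.
#'
#' @param config An [experiment_config()] (or list / YAML path).
#' @param out_dir Optional output directory for the artifact bundle.
#' @return The pipeline result, invisibly when writing a bundle.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  config <- experiment_config(config)
  seed <- config$seed
  net <- config$network %||% list()
  n <- net$n_units %||% 10
  p <- rate_params(n, tau_y = net$tau_y %||% 20, beta = net$beta %||% 0.2,
                   lam = net$lam %||% 20)
  eta <- net$eta %||% 0.1
  dt <- config$dt %||% 0.02

  result <- switch(config$experiment,
    rate = {
      W <- build_sequence_weights(n, eta)
      proto <- config_protocol(config, n, seed)
      sim <- simulate_rate_network(p, W, proto,
                                   duration = config$duration %||% 300,
                                   dt = dt)
      list(kind = "rate", sim = sim, events = sim$trace$events)
    },
    scan = {
      W <- build_sequence_weights(n, eta)
      x_hat <- config$scan$x_hat_in %||% seq(0.3, 0.9, by = 0.1)
      tab <- scan_switch_times(p, W, xin = x_hat * (1 - eta), eta = eta,
                               dt = dt)
      list(kind = "scan", table = tab,
           dynamic_range = dynamic_range(tab$mean_T, tab$order_ok))
    },
    train = {
      tr_cfg <- config$training %||% list()
      W0 <- random_weights(n, seed = child_seed(seed, "init-weights"))
      proto <- make_training_protocol(
        kind = tr_cfg$kind %||% "sinusoids", n_units = n,
        cycle_length = tr_cfg$cycle_length %||% (25 * p$tau_y),
        cycles = tr_cfg$cycles %||% 20,
        probe_level = tr_cfg$probe_level %||% 0.2,
        tau_y = p$tau_y, seed = child_seed(seed, "protocol"))
      pl <- config$plasticity %||% list()
      run <- train_network(W0, proto,
                           plasticity_params(pl$alpha1 %||% 0.05,
                                             pl$alpha2 %||% 0.02,
                                             pl$tau_w %||% 3),
                           p, dt = dt)
      score <- weight_structure_score(run$W, run$taught_order)
      out <- list(kind = "train", run = run, structure = score)
      pert <- config$perturbation
      if (!is.null(pert))
        out$W_perturbed <- perturb_weights(run$W, pert$p %||% 0.1,
                                           seed = child_seed(seed, "perturb"))
      out
    },
    ei = {
      ep <- ei_params(n_units = n, beta = net$beta %||% 0.2,
                      tau_y = net$tau_y %||% 20, lam = net$lam %||% 20)
      lv <- config$scan$levels %||% seq(0.15, 0.6, by = 0.05)
      tab <- scan_ei_periods(ep, lv, dt = dt)
      list(kind = "ei", table = tab,
           dynamic_range = dynamic_range(tab$mean_T, tab$order_ok))
    },
    spiking = {
      sp_cfg <- config$spiking %||% list()
      netw <- build_clustered_network(
        n_clusters = sp_cfg$n_clusters %||% 8,
        cluster_size = sp_cfg$cluster_size %||% 50,
        p_connect = sp_cfg$p_connect %||% 0.2,
        seed = child_seed(seed, "connectivity"))
      sp <- spiking_params(Q = sp_cfg$Q %||% (1.5 * 100 / (sp_cfg$cluster_size %||% 50)))
      training <- train_spiking_network(
        netw, cycles = sp_cfg$cycles %||% 40,
        input_params = sin8_params(seed = child_seed(seed, "tutor-noise")),
        params = sp)
      lv <- sp_cfg$tonic_levels %||% c(0.57, 0.58, 0.59, 0.60, 0.62)
      tab <- spiking_tonic_scan(training$network, lv, training$taught_order,
                                params = sp)
      list(kind = "spiking", training = training, table = tab,
           cluster_weights = cluster_average_weights(training$network$W,
                                                     netw$membership,
                                                     netw$conn))
    })

  if (!is.null(out_dir)) {
    save_bundle(result, out_dir, config = config)
    return(invisible(result))
  }
  result
}

config_protocol <- function(config, n, seed) {
  pr <- config$protocol %||% list(kind = "tonic", level = 0.54)
  switch(pr$kind %||% "tonic",
    tonic = protocol_tonic(n, pr$level %||% 0.54,
                           mask = if (!is.null(pr$mask)) as.logical(pr$mask)),
    pulses = protocol_pulses(n, order = pr$order %||% seq_len(n),
                             cycle_length = pr$cycle_length %||% 200,
                             cycles = pr$cycles %||% 2,
                             amplitude = pr$level %||% 1.5),
    sinusoids = protocol_sinusoids(n, cycle_length = pr$cycle_length %||% 200,
                                   cycles = pr$cycles %||% 2,
                                   seed = child_seed(seed, "protocol")),
    cfg_stop("protocol.kind: unknown kind"))
}

#' Save / load an artifact bundle
#'
#' Writes a result from [run_experiment()] to a directory of plain-text
#' artifacts: `manifest.json` (format version, experiment kind, file list),
#' `config.yaml` when a config is supplied, and CSVs for whatever the
#' result contains (sequence events, scan tables, weight matrices, spike
#' rasters).  `load_bundle()` reads the directory back and checks the
#' format version; a missing or mismatched manifest is an error, not silent
#' corruption.
#'
#' @param result A result list from [run_experiment()].
#' @param path Bundle directory (created if needed).
#' @param config Optional config to store alongside.
#' @return `save_bundle()`: `path`, invisibly.  `load_bundle()`: list with
#'   `manifest`, `config` and the re-read tables/matrices.
#' @export
save_bundle <- function(result, path, config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    write.csv(df, file.path(path, name), row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(result$events)) put(result$events, "events.csv")
  if (!is.null(result$table)) put(result$table, "scan.csv")
  if (!is.null(result$run)) {
    put(as.data.frame(result$run$W), "weights.csv")
    put(result$run$trace$events, "events.csv")
  }
  if (!is.null(result$sim) && inherits(result$sim, "rate_sim")) {
    tidy <- data.frame(time = rep(result$sim$t, ncol(result$sim$x)),
                       unit = rep(seq_len(ncol(result$sim$x)),
                                  each = length(result$sim$t)),
                       x = as.vector(result$sim$x),
                       y = as.vector(result$sim$y))
    put(tidy, "trace.csv")
  }
  if (!is.null(result$training)) {
    put(as.data.frame(result$training$network$W), "weights.csv")
    put(result$training$sim$raster, "raster.csv")
    put(as.data.frame(result$cluster_weights), "cluster_weights.csv")
  }
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(path, "config.yaml"))
  manifest <- list(format = "striatseq-bundle", version = 1L,
                   kind = result$kind, files = as.list(files),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a striatseq bundle: missing manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "striatseq-bundle") ||
      !identical(as.integer(manifest$version), 1L))
    stop("unsupported bundle format/version: ",
         manifest$format, " v", manifest$version)
  out <- list(manifest = manifest)
  for (f in manifest$files) {
    if (!file.exists(file.path(path, f)))
      stop("bundle is truncated: missing ", f)
    key <- sub("\\.csv$", "", f)
    tab <- read.csv(file.path(path, f))
    out[[key]] <- if (key %in% c("weights", "cluster_weights"))
      unname(as.matrix(tab)) else tab
  }
  cfg <- file.path(path, "config.yaml")
  if (file.exists(cfg)) out$config <- yaml::read_yaml(cfg)
  out
}
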