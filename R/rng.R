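# Seed handling: run code under a temporary seed without disturbing the
# caller's RNG state, and derive independent child seeds from one master
# seed by component name so that adding a component never shifts the
# streams of existing ones.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a stream name
#'
#' Deterministically maps `(master, name)` to an integer below 2^31 so that
#' every stochastic component of an experiment (connectivity, protocol
#' noise, perturbations, ...) gets its own reproducible stream.
#'
#' @param master Master integer seed.
#' @param name Character stream name.
#' @return A single integer seed.
#' @export
child_seed <- function(master, name) {
  if (!is.numeric(master) || length(master) != 1L)
    stop("`master` must be a single number")
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1048573
  as.integer((abs(master) %% 1000003) * 2048 + h %% 2048 + 1)
}
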