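# Seed handling. All stochastic operations take an explicit seed and run in a
# local RNG scope so that callers' random state is never disturbed, and every
# per-image stream is derived from one root seed by a stable counter scheme
# (reproducible regardless of generation order or chunking).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a per-item seed from a root seed and a counter
#'
#' Deterministic stream derivation: item `counter` under root seed `root`
#' always receives the same derived seed, independent of how many other items
#' are generated or in what order. Used to give every synthetic image its own
#' reproducible random stream.
#'
#' @param root integer root seed.
#' @param counter non-negative integer item index (vectorised).
#' @return integer seed(s) in `[0, 2^31 - 2]`.
#' @export
seed_stream <- function(root, counter) {
  p <- 2147483647 # 2^31 - 1
  root <- as.numeric(root) %% p
  counter <- as.numeric(counter)
  stopifnot(all(counter >= 0))
  as.integer((root * 69069 + counter * 1013904223 + 1) %% p)
}
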