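# Condition classes used throughout the package so callers (and the CLI exit
# codes) can distinguish malformed input from estimation failures.

input_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("bayesrma_input_error", "bayesrma_error")))
}

estimation_error <- function(msg) {
  stop(errorCondition(msg, class = c("bayesrma_estimation_error", "bayesrma_error")))
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    input_error("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-replicate seed derived from a root seed. Kept below 2^31
# so it is always a valid R integer seed.
derive_seed <- function(seed, index, stream = 0L) {
  p <- 2147483563
  s <- (as.double(seed) %% p) * 40014
  s <- (s + as.double(index) * 40692 + as.double(stream) * 7919) %% p
  as.integer(s) + 1L
}
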