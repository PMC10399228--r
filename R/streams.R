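# Named RNG streams.
#
# The engine draws from three independent sources of randomness (sensor
# noise, resampling, transition sampling). Keeping them in separate streams
# means that toggling long-term memory, or switching the resampling scheme,
# leaves the sensor-noise realization untouched -- a requirement for
# paired-seed comparisons of adaptation speed.

new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed %% 2147483629L)
  env$state <- NULL
  class(env) <- "grav_rng_stream"
  env
}

# Evaluate `expr` under the stream's RNG state; the global RNG state is
# saved and restored so streams never interfere with each other or with
# user code.
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  result <- force(expr)
  stream$state <- get(".Random.seed", envir = globalenv())
  result
}

# Derive the three engine stream seeds from one master seed, keeping every
# derived seed inside 32-bit integer range.
derive_stream_seeds <- function(seed) {
  base <- as.double(seed) %% 2147483629
  c(
    noise = (base * 3 + 101) %% 2147483629,
    resample = (base * 3 + 211) %% 2147483629,
    transition = (base * 3 + 307) %% 2147483629
  )
}
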