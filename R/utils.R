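# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Deterministic per-component seed derived from a global seed, so that
# toggling one stochastic component does not shift the random stream of the
# others.  Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  offsets <- c(layout = 1, runoff = 2, met = 3, effects = 4, noise = 5,
               fire = 6, population = 7, country = 8, draws = 9,
               ensemble = 10, scalings = 11)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]] * 97) %% 2147483629)
}
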