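# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# One master seed; derived streams use fixed increments so that replicates,
# axes and stages draw from disjoint, reproducible streams. Kept < 2^31.
derive_seed <- function(seed, stream, k = 0L) {
  offsets <- c(truth = 11L, counts = 101L, jitter = 211L, sequences = 307L,
               posterior = 401L, assignment = 503L, evaluation = 601L,
               abundance = 701L)
  off <- offsets[[stream]]
  (as.integer(seed) %% 1000000L) * 1000L + off + 7L * as.integer(k)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

AXES <- c("AP", "DV", "ML")

check_axis <- function(axis) {
  if (length(axis) != 1L || !axis %in% AXES) {
    stopf("`axis` must be one of %s", paste(AXES, collapse = ", "))
  }
  axis
}
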