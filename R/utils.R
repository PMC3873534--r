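# Internal helpers shared across modules.

# Derive a reproducible 31-bit child seed from a master seed and a stream
# index, so that per-unit / per-pair randomness is independent of the order
# in which objects are generated.
derive_seed <- function(master, index) {
  master <- as.double(master) %% 2147483647
  x <- (master * 48271 + as.double(index) * 33941 + 17) %% 2147483629
  as.integer(x + 1)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
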