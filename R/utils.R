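# Internal helpers shared across modules.

# Derive a child seed from a base seed and one or more small offsets.
# Keeps results in [1, 2^31 - 2] so they are valid R integer seeds.
deriveSeed <- function(seed, ...) {
  off <- c(...)
  v <- as.double(seed)
  for (o in off) v <- (v * 69069 + as.double(o) + 1) %% 2147483647
  as.integer(v) + 1L
}

# Evaluate an expression with a local RNG state (does not disturb the
# caller's .Random.seed).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopIf <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

# positive class used for probabilities, AUC and subject aggregation
POSITIVE_CLASS <- "patient"
NEGATIVE_CLASS <- "control"
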