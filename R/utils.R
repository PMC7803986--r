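# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label; keeps distinct
# consumers (shuffling, head init, blob placement, ...) on distinct streams
# while staying inside 32-bit integer range.
deriveSeed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + s * 9973) %% 2147483647)
}

# round-half-up, used for the validation split size
roundHalfUp <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

isCount <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x)
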