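## Internal utilities: deterministic hashing, pair keys, local RNG scope.

## Polynomial rolling hashes over a prime modulus below 2^26.  Every
## intermediate product stays below 2^53, so plain double arithmetic is exact.
.HASH_MOD <- 67108859

.polyHash <- function(ints, mult, init = 5381) {
  h <- init %% .HASH_MOD
  for (v in ints) h <- (h * mult + v) %% .HASH_MOD
  h
}

## Deterministic hash of a character scalar to an integer in [0, .HASH_MOD).
stringHash <- function(s, mult = 31) {
  .polyHash(utf8ToInt(s), mult)
}

## Deterministic hash of a non-negative integer vector.
intVecHash <- function(v, mult = 131) {
  .polyHash(v %% .HASH_MOD, mult)
}

## Deterministic uniform deviate in [0, 1) derived from a string key.  Two
## independent polynomial hashes supply ~52 bits of state; used by the mock
## backends so that identical prompts always receive identical answers.
hashUnit <- function(key) {
  ints <- utf8ToInt(key)
  h1 <- .polyHash(ints, 31L)
  h2 <- .polyHash(ints, 131L, init = 104729)
  (h1 * 67108864 + h2) / (.HASH_MOD * 67108864)
}

## Canonical unordered pair key: lexicographically sorted ids joined by "|".
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

## Sort each row of a two-column id matrix lexicographically.
canonicalPairs <- function(pairs) {
  if (!is.matrix(pairs)) pairs <- matrix(pairs, ncol = 2)
  cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

## Derive a child seed below 2^31 from a base seed and a stream label.
childSeed <- function(seed, label) {
  as.integer((abs(seed) + stringHash(as.character(label))) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
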