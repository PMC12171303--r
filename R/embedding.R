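## Embedding provider contract.
##
## The contract is: given a SMILES string, return a fixed-dimension numeric
## vector. The default provider is a deterministic character-n-gram hashing
## embedding: reproducible everywhere, no pretrained weights, no seed. A
## pretrained-transformer provider can be dropped in through the same
## contract (any function(smiles, dim) -> numeric(dim)); it is deliberately
## outside the test path.

#' Deterministic character-n-gram hashing embedding of a SMILES string
#'
#' Counts all character n-grams (n = 1..3) of the canonical SMILES, feature-
#' hashes each n-gram to one of `dim` signed buckets, and L2-normalizes. Two
#' SMILES spellings of the same molecule map to the same vector because the
#' string is canonicalized first.
#'
#' @param smiles a single SMILES string.
#' @param dim embedding dimension (default 64).
#' @return numeric vector of length `dim` with unit norm.
#' @examples
#' e <- smilesEmbedding("CCO")
#' sum(e^2)
#' @export
smilesEmbedding <- function(smiles, dim = 64) {
  stopifnot(length(smiles) == 1, dim >= 2)
  s <- canonicalizeSmiles(smiles)
  if (is.na(s)) stop("invalid SMILES: ", smiles)
  chars <- strsplit(s, "")[[1]]
  v <- numeric(dim)
  for (n in 1:3) {
    if (length(chars) < n) break
    for (i in seq_len(length(chars) - n + 1)) {
      gram <- paste(chars[i:(i + n - 1)], collapse = "")
      h <- stringHash(gram)
      idx <- (h %% dim) + 1
      sgn <- if (stringHash(gram, mult = 131) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) { v[1] <- 1; nrm <- 1 }  # degenerate one-char molecules
  v / nrm
}
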