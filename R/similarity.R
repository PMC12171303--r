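## The five drug-drug similarity measures: Tanimoto, binary cosine and Dice
## on fingerprints; the Weisfeiler-Lehman graph kernel; embedding cosine.

## Accept a Fingerprint or a raw 0/1 vector and return on-bit positions.
.bitPositions <- function(x) {
  if (is(x, "Fingerprint")) return(x@bits)
  v <- as.integer(x)
  if (!all(v %in% c(0L, 1L))) stop("binary vector expected")
  which(v == 1L)
}

.bitCounts <- function(x, y) {
  bx <- .bitPositions(x); by <- .bitPositions(y)
  if (length(bx) == 0 && length(by) == 0)
    stop("similarity undefined: both fingerprints are all-zero")
  c(a = length(bx), b = length(by), ab = length(intersect(bx, by)))
}

#' Tanimoto similarity of binary fingerprints
#'
#' `sum(x*y) / (sum(x^2) + sum(y^2) - sum(x*y))`: shared substructures over
#' the total number of distinct substructures across both molecules.
#'
#' @param x,y [Fingerprint-class] objects or raw 0/1 vectors of equal
#'   length. Both all-zero is an error (a silent 0 would corrupt top-k
#'   ranking downstream).
#' @return score in `[0,1]`.
#' @examples
#' tanimotoSimilarity(c(1, 1, 1, 0), c(0, 1, 1, 1))
#' @export
tanimotoSimilarity <- function(x, y) {
  n <- .bitCounts(x, y)
  n[["ab"]] / (n[["a"]] + n[["b"]] - n[["ab"]])
}

#' Cosine similarity of binary fingerprints
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`.
#'
#' @inheritParams tanimotoSimilarity
#' @return score in `[0,1]`.
#' @export
cosineBinarySimilarity <- function(x, y) {
  n <- .bitCounts(x, y)
  if (n[["a"]] == 0 || n[["b"]] == 0) return(0)
  n[["ab"]] / sqrt(n[["a"]] * n[["b"]])
}

#' Dice similarity of binary fingerprints
#'
#' `2 * sum(x*y) / (sum(x^2) + sum(y^2))`.
#'
#' @inheritParams tanimotoSimilarity
#' @return score in `[0,1]`.
#' @export
diceSimilarity <- function(x, y) {
  n <- .bitCounts(x, y)
  2 * n[["ab"]] / (n[["a"]] + n[["b"]])
}

## ---------------------------------------------------------------------------
## Weisfeiler-Lehman subtree kernel
## ---------------------------------------------------------------------------

#' Weisfeiler-Lehman feature map of a molecular graph
#'
#' Runs `h` rounds of WL label refinement starting from element-symbol node
#' labels: at each round a node's label becomes its previous label joined
#' with the sorted multiset of its neighbours' previous labels. The feature
#' map counts every (iteration, label) pattern for iterations `0..h`; labels
#' are kept as explicit strings, which makes maps from different graphs
#' directly comparable without a shared dictionary.
#'
#' @param g a [MolGraph-class].
#' @param h number of refinement iterations (`>= 0`).
#' @return named integer vector of pattern counts; the total count is
#'   `n_nodes * (h + 1)`.
#' @export
wlFeatureMap <- function(g, h = 3) {
  if (length(g@nodes) == 0) stop("empty graph")
  stopifnot(h >= 0)
  nbr <- .adjacency(g)
  labels <- g@nodes
  feats <- paste0("0:", labels)
  if (h > 0) for (r in seq_len(h)) {
    labels <- vapply(seq_along(labels), function(i) {
      ns <- sort(labels[nbr[[i]]])
      paste0(labels[i], "(", paste(ns, collapse = ","), ")")
    }, character(1))
    feats <- c(feats, paste0(r, ":", labels))
  }
  tab <- table(feats)
  stats::setNames(as.integer(tab), names(tab))
}

#' Weisfeiler-Lehman graph kernel
#'
#' Dot product of the WL feature maps of the two graphs, summed over
#' refinement iterations `0..h`; optionally normalized to
#' `K / sqrt(K11 * K22)` so that self-similarity is 1.
#'
#' @param g1,g2 [MolGraph-class] objects (non-empty).
#' @param h refinement iterations (default 3).
#' @param normalized return the normalized kernel (default `TRUE`).
#' @return kernel value; in `[0,1]` when normalized.
#' @examples
#' g <- molGraphFromSmiles("CCO")
#' wlKernel(g, g)
#' @export
wlKernel <- function(g1, g2, h = 3, normalized = TRUE) {
  m1 <- wlFeatureMap(g1, h); m2 <- wlFeatureMap(g2, h)
  .wlDot <- function(a, b) {
    common <- intersect(names(a), names(b))
    if (!length(common)) return(0)
    sum(as.numeric(a[common]) * as.numeric(b[common]))
  }
  k <- .wlDot(m1, m2)
  if (!normalized) return(k)
  k / sqrt(.wlDot(m1, m1) * .wlDot(m2, m2))
}

## ---------------------------------------------------------------------------
## Embedding cosine
## ---------------------------------------------------------------------------

#' Cosine similarity of embedding vectors
#'
#' @param ex,ey numeric vectors of equal dimension with nonzero norm.
#' @return score in `[-1,1]`.
#' @examples
#' embeddingSimilarity(c(1, 1), c(1, 0))
#' @export
embeddingSimilarity <- function(ex, ey) {
  stopifnot(length(ex) == length(ey))
  if (!all(is.finite(ex)) || !all(is.finite(ey)))
    stop("embeddings must be finite")
  nx <- sqrt(sum(ex^2)); ny <- sqrt(sum(ey^2))
  if (nx == 0 || ny == 0) stop("zero-norm embedding")
  sum(ex * ey) / (nx * ny)
}

## ---------------------------------------------------------------------------
## Dispatch and library-level similarity matrices
## ---------------------------------------------------------------------------

#' Similarity between two drugs under a chosen metric
#'
#' Routes to the fingerprint, graph-kernel or embedding measure named by
#' `metric`. All metrics share the `[0,1]` range: the embedding cosine is
#' clamped at 0 from below so that scores compose in the pair-product rule.
#'
#' @param library a [DrugLibrary-class].
#' @param a,b drug ids.
#' @param metric one of `tanimoto`, `cosine`, `dice`, `graph_wl`,
#'   `embedding`.
#' @param config a [RunConfig-class] supplying fingerprint/WL/embedding
#'   parameters.
#' @return score in `[0,1]`.
#' @export
drugSimilarity <- function(library, a, b, metric = "tanimoto",
                           config = runConfig()) {
  stopifnot(metric %in% .SIM_METRICS)
  sm <- drugSmiles(library)
  if (!all(c(a, b) %in% names(sm))) stop("unknown drug id")
  if (metric %in% c("tanimoto", "cosine", "dice")) {
    fa <- morganFingerprint(sm[[a]], config@fingerprintRadius,
                            config@fingerprintBits)
    fb <- morganFingerprint(sm[[b]], config@fingerprintRadius,
                            config@fingerprintBits)
    return(switch(metric,
                  tanimoto = tanimotoSimilarity(fa, fb),
                  cosine = cosineBinarySimilarity(fa, fb),
                  dice = diceSimilarity(fa, fb)))
  }
  if (metric == "graph_wl") {
    return(wlKernel(molGraphFromSmiles(sm[[a]]), molGraphFromSmiles(sm[[b]]),
                    h = config@wlIterations, normalized = TRUE))
  }
  max(0, embeddingSimilarity(smilesEmbedding(sm[[a]], config@embeddingDim),
                             smilesEmbedding(sm[[b]], config@embeddingDim)))
}

#' All-pairs drug similarity matrix
#'
#' Computes the full symmetric similarity matrix of a library under one
#' metric, vectorized over fingerprint bit counts for the binary metrics.
#' Retrieval and cross-validation precompute this once per run.
#'
#' @inheritParams drugSimilarity
#' @return symmetric numeric matrix with unit diagonal, dimnames = drug ids.
#' @export
similarityMatrix <- function(library, metric = "tanimoto",
                             config = runConfig()) {
  stopifnot(metric %in% .SIM_METRICS)
  ids <- drugIds(library)
  n <- length(ids)
  if (metric %in% c("tanimoto", "cosine", "dice")) {
    M <- fingerprintMatrix(library, config@fingerprintRadius,
                           config@fingerprintBits)
    ab <- tcrossprod(M)
    cnt <- rowSums(M)
    if (any(cnt == 0)) stop("all-zero fingerprint in library")
    A <- matrix(cnt, n, n); B <- t(A)
    S <- switch(metric,
                tanimoto = ab / (A + B - ab),
                cosine = ab / sqrt(A * B),
                dice = 2 * ab / (A + B))
  } else if (metric == "graph_wl") {
    graphs <- .molGraphs(drugSmiles(library))
    maps <- lapply(graphs, wlFeatureMap, h = config@wlIterations)
    allNames <- unique(unlist(lapply(maps, names)))
    F <- matrix(0, n, length(allNames))
    for (i in seq_len(n)) F[i, match(names(maps[[i]]), allNames)] <- maps[[i]]
    K <- tcrossprod(F)
    d <- sqrt(diag(K))
    S <- K / outer(d, d)
  } else {
    E <- t(vapply(drugSmiles(library), smilesEmbedding,
                  numeric(config@embeddingDim), dim = config@embeddingDim))
    E <- E / sqrt(rowSums(E^2))
    S <- pmax(tcrossprod(E), 0)
  }
  S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}
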