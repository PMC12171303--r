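## Exemplar retrieval: top-k most similar known-interacting pairs (positive
## prompts) and top-k most similar non-interacting pairs (hard negatives).

## Vectorized pair-product score of one query against candidate id vectors.
## Pairs are unordered, so the score is the better of the two drug-to-drug
## assignments.
.pairScores <- function(S, q1, q2, c1, c2) {
  s1 <- S[q1, ][c1] * S[q2, ][c2]
  s2 <- S[q1, ][c2] * S[q2, ][c1]
  list(score = pmax(s1, s2),
       matching = ifelse(s1 >= s2, "direct", "swapped"))
}

#' Pair-product similarity between two drug pairs
#'
#' The similarity of two unordered pairs is the product of the two drug-drug
#' similarities, maximized over the two possible drug-to-drug assignments
#' (`direct`: q1-c1/q2-c2, `swapped`: q1-c2/q2-c1).
#'
#' @param library a [DrugLibrary-class].
#' @param query,candidate character vectors of two drug ids each.
#' @param metric similarity metric (see [drugSimilarity()]).
#' @param config a [RunConfig-class].
#' @param simMatrix optional precomputed [similarityMatrix()].
#' @return list with `score` in `[0,1]` and `matching`.
#' @export
pairSimilarity <- function(library, query, candidate, metric = "tanimoto",
                           config = runConfig(), simMatrix = NULL) {
  stopifnot(length(query) == 2, length(candidate) == 2)
  if (is.null(simMatrix)) {
    s11 <- drugSimilarity(library, query[1], candidate[1], metric, config)
    s22 <- drugSimilarity(library, query[2], candidate[2], metric, config)
    s12 <- drugSimilarity(library, query[1], candidate[2], metric, config)
    s21 <- drugSimilarity(library, query[2], candidate[1], metric, config)
    a <- s11 * s22; b <- s12 * s21
    return(list(score = max(a, b),
                matching = if (a >= b) "direct" else "swapped"))
  }
  r <- .pairScores(simMatrix, query[1], query[2], candidate[1], candidate[2])
  list(score = unname(r$score[1]), matching = unname(r$matching[1]))
}

## Leakage filter over candidate pair id columns.
.applyLeakage <- function(c1, c2, query, policy) {
  qk <- pairKey(query[1], query[2])
  if (policy == "exclude_drugs")
    !(c1 %in% query | c2 %in% query)
  else
    pairKey(c1, c2) != qk
}

## Rank candidates by (descending score, lexicographic canonical pair key)
## and keep the top k.
.rankTopK <- function(c1, c2, score, matching, k) {
  key <- pairKey(c1, c2)
  ord <- order(-score, key)
  take <- utils::head(ord, k)
  data.frame(id1 = pmin(c1[take], c2[take]),
             id2 = pmax(c1[take], c2[take]),
             score = score[take], matching = matching[take],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select positive in-context exemplars for a query pair
#'
#' Ranks all known-interacting pairs by pair-product similarity to the query
#' and returns the top `k`, after removing candidates excluded by the
#' leakage policy. Ties are broken by the lexicographic canonical pair key.
#'
#' @param query character vector of two drug ids.
#' @param interactions an [InteractionSet-class] of known positives.
#' @param k number of exemplars (`>= 0`); if fewer candidates exist, all are
#'   returned with a warning.
#' @param config a [RunConfig-class] (metric, leakage policy).
#' @param simMatrix optional precomputed [similarityMatrix()] over the
#'   interaction set's universe.
#' @return data.frame of exemplars (`id1`, `id2`, `score`, `matching`),
#'   sorted by descending score.
#' @export
selectPositiveExemplars <- function(query, interactions, k,
                                    config = runConfig(), simMatrix = NULL) {
  stopifnot(k >= 0)
  if (k == 0) return(.rankTopK(character(), character(), numeric(),
                               character(), 0))
  if (nInteractions(interactions) == 0)
    stop("no known interactions to draw positive exemplars from")
  if (is.null(simMatrix))
    simMatrix <- similarityMatrix(universe(interactions),
                                  config@similarityMetric, config)
  p <- interactionPairs(interactions)
  keep <- .applyLeakage(p[, 1], p[, 2], query, config@leakagePolicy)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0) {
    warning("no positive exemplar candidates after leakage exclusion")
    return(.rankTopK(character(), character(), numeric(), character(), 0))
  }
  sc <- .pairScores(simMatrix, query[1], query[2], p[, 1], p[, 2])
  if (nrow(p) < k)
    warning(sprintf("only %d positive exemplar(s) available (k = %d)",
                    nrow(p), k))
  .rankTopK(p[, 1], p[, 2], sc$score, sc$matching, k)
}

## All unordered non-interacting pairs of the library, as a two-column
## matrix, minus extra exclusions (canonical pair keys).
.negativeUniverse <- function(library, interactions, exclude = character()) {
  ids <- sort(drugIds(library))
  n <- length(ids)
  if (n < 2) stop("library too small to form any negative pair")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  c1 <- ids[idx[, 1]]; c2 <- ids[idx[, 2]]
  key <- pairKey(c1, c2)
  posKey <- pairKey(interactionPairs(interactions)[, 1],
                    interactionPairs(interactions)[, 2])
  keep <- !(key %in% posKey) & !(key %in% exclude)
  cbind(c1[keep], c2[keep])
}

#' Mine hard negative exemplars for a query pair
#'
#' Hard negatives are the non-interacting pairs most similar to the query:
#' maximally informative "no" demonstrations. The candidate universe is
#' every unordered drug pair absent from the interaction set; when it
#' exceeds `config@candidateCap`, a seeded uniform subsample of that size is
#' ranked instead. Same tie rule as the positive selector.
#'
#' @inheritParams selectPositiveExemplars
#' @param library a [DrugLibrary-class].
#' @param exclude character vector of canonical pair keys to exclude from
#'   the candidate universe (e.g. held-out evaluation negatives).
#' @param seed seed for the subsample (defaults to the config seed).
#' @param universe optional precomputed non-edge matrix (two id columns), as
#'   built internally from `library` and `interactions`; callers evaluating
#'   many queries against the same universe precompute it once.
#' @return data.frame of exemplars, sorted by descending score.
#' @export
mineHardNegatives <- function(query, library, interactions, k,
                              config = runConfig(), simMatrix = NULL,
                              exclude = character(), seed = NULL,
                              universe = NULL) {
  stopifnot(k >= 0)
  if (k == 0) return(.rankTopK(character(), character(), numeric(),
                               character(), 0))
  if (is.null(simMatrix))
    simMatrix <- similarityMatrix(library, config@similarityMetric, config)
  u <- universe %||% .negativeUniverse(library, interactions, exclude)
  keep <- .applyLeakage(u[, 1], u[, 2], query, config@leakagePolicy)
  u <- u[keep, , drop = FALSE]
  if (nrow(u) == 0) stop("no negative pair candidates available")
  if (nrow(u) > config@candidateCap) {
    seed <- seed %||% childSeed(config@seed, "negative_cap")
    take <- withSeed(seed, sample.int(nrow(u), config@candidateCap))
    u <- u[sort(take), , drop = FALSE]
  }
  sc <- .pairScores(simMatrix, query[1], query[2], u[, 1], u[, 2])
  if (nrow(u) < k)
    warning(sprintf("only %d negative exemplar(s) available (k = %d)",
                    nrow(u), k))
  .rankTopK(u[, 1], u[, 2], sc$score, sc$matching, k)
}

#' Build the full exemplar set for a query pair
#'
#' Composes [selectPositiveExemplars()] and [mineHardNegatives()] into an
#' [ExemplarSet-class].
#'
#' @inheritParams mineHardNegatives
#' @param k exemplars per label (defaults to `config@kExemplars`).
#' @return An [ExemplarSet-class].
#' @examples
#' w <- generateWorld(nDrugs = 12, baseRate = 0.2, lambda = 4, seed = 1)
#' q <- interactionPairs(w@interactions)[1, ]
#' buildExemplarSet(q, w@library, w@interactions, k = 2)
#' @export
buildExemplarSet <- function(query, library, interactions,
                             k = config@kExemplars, config = runConfig(),
                             simMatrix = NULL, exclude = character(),
                             seed = NULL) {
  if (is.null(simMatrix))
    simMatrix <- similarityMatrix(library, config@similarityMetric, config)
  pos <- selectPositiveExemplars(query, interactions, k, config, simMatrix)
  neg <- mineHardNegatives(query, library, interactions, k, config,
                           simMatrix, exclude, seed)
  new("ExemplarSet", positives = pos, negatives = neg, k = as.integer(k),
      metric = config@similarityMetric,
      query = c(min(query), max(query)))
}

#' Randomly drawn exemplar set (retrieval baseline)
#'
#' Draws `k` positives and `k` negatives uniformly at random instead of by
#' similarity; retrieval scores are still attached and each list is sorted
#' by descending score, so prompts render identically in structure. Used as
#' the control against similarity-driven retrieval.
#'
#' @inheritParams mineHardNegatives
#' @param seed seed for the draw.
#' @return An [ExemplarSet-class].
#' @export
randomExemplarSet <- function(query, library, interactions,
                              k = config@kExemplars, config = runConfig(),
                              simMatrix = NULL, exclude = character(),
                              seed = 1, universe = NULL) {
  if (is.null(simMatrix))
    simMatrix <- similarityMatrix(library, config@similarityMetric, config)
  p <- interactionPairs(interactions)
  keep <- .applyLeakage(p[, 1], p[, 2], query, config@leakagePolicy)
  p <- p[keep, , drop = FALSE]
  u <- universe %||% .negativeUniverse(library, interactions, exclude)
  keep <- .applyLeakage(u[, 1], u[, 2], query, config@leakagePolicy)
  u <- u[keep, , drop = FALSE]
  pi <- withSeed(childSeed(seed, "rand_pos"),
                 sample.int(nrow(p), min(k, nrow(p))))
  ni <- withSeed(childSeed(seed, "rand_neg"),
                 sample.int(nrow(u), min(k, nrow(u))))
  mk <- function(m, take) {
    m <- m[take, , drop = FALSE]
    if (nrow(m) == 0)
      return(.rankTopK(character(), character(), numeric(), character(), 0))
    sc <- .pairScores(simMatrix, query[1], query[2], m[, 1], m[, 2])
    .rankTopK(m[, 1], m[, 2], sc$score, sc$matching, nrow(m))
  }
  new("ExemplarSet", positives = mk(p, pi), negatives = mk(u, ni),
      k = as.integer(k), metric = "random",
      query = c(min(query), max(query)))
}

## ---------------------------------------------------------------------------
## Internal fast retrieval path for cross-validation
##
## The public per-query selectors above are the documented reference surface;
## run_cv evaluates thousands of queries against the same candidate sets, so
## it precomputes integer candidate indices and lexicographic tie ranks once
## per fold and ranks with numeric keys only. Equality with the public path
## is asserted in the test suite.
## ---------------------------------------------------------------------------

## Precompute integer index/tie-rank structures for a canonical pair matrix.
.pairCandidates <- function(ids, pairs) {
  if (nrow(pairs) == 0)
    return(list(i1 = integer(), i2 = integer(), tie = integer(),
                id1 = character(), id2 = character()))
  key <- pairKey(pairs[, 1], pairs[, 2])
  list(i1 = match(pairs[, 1], ids), i2 = match(pairs[, 2], ids),
       tie = match(key, sort(key)), id1 = pairs[, 1], id2 = pairs[, 2])
}

## Leakage mask over precomputed candidates for a query (integer indices).
.candidateKeep <- function(cand, qa, qb, policy) {
  if (policy == "exclude_drugs")
    !(cand$i1 == qa | cand$i1 == qb | cand$i2 == qa | cand$i2 == qb)
  else
    !((cand$i1 == qa & cand$i2 == qb) | (cand$i1 == qb & cand$i2 == qa))
}

## Top-k candidates for one query under the documented
## (descending score, lexicographic canonical key) tie rule.
.topCandidates <- function(cand, S, qa, qb, k, policy) {
  keep <- .candidateKeep(cand, qa, qb, policy)
  r1 <- S[qa, ]; r2 <- S[qb, ]
  s1 <- r1[cand$i1] * r2[cand$i2]
  s2 <- r1[cand$i2] * r2[cand$i1]
  sc <- pmax(s1, s2)
  sc[!keep] <- -1
  take <- order(-sc, cand$tie)[seq_len(min(k, sum(keep)))]
  data.frame(id1 = cand$id1[take], id2 = cand$id2[take],
             score = sc[take],
             matching = c("swapped", "direct")[(s1[take] >= s2[take]) + 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

## Seeded uniform draw of k candidates (random-retrieval baseline), scored
## and sorted like the similarity path.
.randomCandidates <- function(cand, S, qa, qb, k, policy, seed) {
  keep <- which(.candidateKeep(cand, qa, qb, policy))
  take <- withSeed(seed, keep[sample.int(length(keep), min(k, length(keep)))])
  r1 <- S[qa, ]; r2 <- S[qb, ]
  s1 <- r1[cand$i1[take]] * r2[cand$i2[take]]
  s2 <- r1[cand$i2[take]] * r2[cand$i1[take]]
  sc <- pmax(s1, s2)
  ord <- order(-sc, cand$tie[take])
  data.frame(id1 = cand$id1[take][ord], id2 = cand$id2[take][ord],
             score = sc[ord],
             matching = ifelse(s1[ord] >= s2[ord], "direct", "swapped"),
             stringsAsFactors = FALSE, row.names = NULL)
}
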