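## Ranking metrics (AUC, AUPR) and the k-fold cross-validation harness.

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, with half credit for ties, computed from
#' midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), at least one of each class.
#' @return AUC in `[0,1]`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(scores)  # midranks share credit across ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: the mean of the precision values at the
#' rank of each positive, walking down the ranking by descending score
#' (ties broken by stable original order).
#'
#' @inheritParams rocAuc
#' @return AUPR in `(0,1]`.
#' @examples
#' averagePrecision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (sum(labels == 1) == 0) stop("AUPR undefined: no positive labels")
  ord <- order(-scores)  # stable: ties keep original order
  y <- labels[ord]
  cumPos <- cumsum(y)
  prec <- cumPos / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Stratified k-fold split of a labeled pair list
#'
#' Seeded random partition into `folds` near-equal subsets, stratified by
#' label so each fold carries the overall class balance; every element lands
#' in exactly one test fold.
#'
#' @param labels binary label vector (one entry per pair).
#' @param folds number of folds (`>= 2`).
#' @param seed split seed.
#' @return list of length `folds`; element `i` is `list(train=, test=)`
#'   index vectors.
#' @export
kfoldSplit <- function(labels, folds = 10, seed = 1) {
  n <- length(labels)
  stopifnot(folds >= 2)
  if (n < folds) stop("too few pairs for the requested fold count")
  assign <- integer(n)
  withSeed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

## Sample `m` evaluation negatives (non-edges) uniformly, seeded.
.sampleEvalNegatives <- function(library, interactions, m, seed) {
  u <- .negativeUniverse(library, interactions)
  if (nrow(u) < m) stop("not enough non-edges for evaluation negatives")
  take <- withSeed(seed, sample.int(nrow(u), m))
  u[sort(take), , drop = FALSE]
}

#' Cross-validated evaluation of the prediction pipeline
#'
#' Runs stratified k-fold cross-validation over the known interactions plus
#' an equal-sized (times `negativeRatio`) seeded sample of non-edges. For
#' each fold, in-context exemplars are retrieved only from that fold's
#' training positives and from non-edges never used as that fold's test
#' negatives (train/test separation is asserted); every test pair is scored
#' by the backend roster, fused (judge-weighted when a judge is given,
#' uniform otherwise), and the fold's AUC and AUPR are computed on the fused
#' score `S_final`. When a judge runs, per-fold uniform-fusion metrics are
#' reported alongside for comparison.
#'
#' @param library a [DrugLibrary-class].
#' @param interactions an [InteractionSet-class] (the positive class).
#' @param backends list of prediction [BackendSpec-class] objects.
#' @param config a [RunConfig-class]; `config@kExemplars = 0` runs
#'   zero-shot prompts.
#' @param judge optional judge [BackendSpec-class].
#' @param folds number of CV folds (default 10).
#' @param negativeRatio evaluation negatives per positive (default 1).
#' @param retrieval `similarity` (default) or `random` exemplar retrieval.
#' @param ks optional integer vector of exemplar counts: evaluates every
#'   `k` in one pass (sharing retrieval work) and returns a named list of
#'   reports `k0`, `k1`, ... instead of a single report.
#' @param keepDetails keep per-query records in `report@details`.
#' @return An [EvalReport-class], or a named list of them when `ks` is
#'   given.
#' @export
runCV <- function(library, interactions, backends, config = runConfig(),
                  judge = NULL, folds = 10, negativeRatio = 1,
                  retrieval = c("similarity", "random"), ks = NULL,
                  keepDetails = FALSE) {
  retrieval <- match.arg(retrieval)
  if (!is.list(backends)) backends <- list(backends)
  singleK <- is.null(ks)
  if (singleK) ks <- config@kExemplars
  ks <- as.integer(ks)
  maxK <- max(ks)
  seed <- config@seed
  ids <- drugIds(library)
  S <- if (maxK > 0)
    similarityMatrix(library, config@similarityMetric, config) else NULL

  pos <- interactionPairs(interactions)
  nPos <- nrow(pos)
  if (nPos < folds) stop("fewer positive pairs than folds")
  neg <- .sampleEvalNegatives(library, interactions,
                              round(nPos * negativeRatio),
                              childSeed(seed, "eval_negatives"))
  pairs <- rbind(pos, neg)
  labels <- rep(1:0, c(nPos, nrow(neg)))
  keys <- pairKey(pairs[, 1], pairs[, 2])
  split <- kfoldSplit(labels, folds, childSeed(seed, "fold_split"))

  perK <- stats::setNames(
    lapply(ks, function(k) vector("list", folds)), paste0("k", ks))
  foldStatus <- character(folds)

  for (f in seq_len(folds)) {
    res <- tryCatch({
      testIdx <- split[[f]]$test
      ## shuffle test order so stable-order tie-breaking in the metrics is
      ## not biased by the positives-first construction of the pair list
      testIdx <- testIdx[withSeed(childSeed(seed, paste("shuffle", f)),
                                  sample.int(length(testIdx)))]
      testPairs <- pairs[testIdx, , drop = FALSE]
      testLabels <- labels[testIdx]
      testKeys <- keys[testIdx]
      trainPosIdx <- intersect(split[[f]]$train, which(labels == 1))
      trainIS <- InteractionSet(pairs[trainPosIdx, , drop = FALSE], library)
      posCand <- negCand <- NULL
      if (maxK > 0) {
        negUniverse <- .negativeUniverse(library, interactions,
                                         exclude = testKeys)
        if (nrow(negUniverse) > config@candidateCap) {
          take <- withSeed(childSeed(seed, paste("negative_cap", f)),
                           sample.int(nrow(negUniverse), config@candidateCap))
          negUniverse <- negUniverse[sort(take), , drop = FALSE]
        }
        posCand <- .pairCandidates(ids, interactionPairs(trainIS))
        negCand <- .pairCandidates(ids, negUniverse)
      }

      scoreK <- matrix(NA_real_, length(testIdx), length(ks))
      scoreKUnif <- matrix(NA_real_, length(testIdx), length(ks))
      details <- if (keepDetails) vector("list", length(testIdx)) else NULL

      for (i in seq_along(testIdx)) {
        q <- sort(testPairs[i, ])
        es <- NULL
        if (maxK > 0) {
          qa <- match(q[1], ids); qb <- match(q[2], ids)
          pol <- config@leakagePolicy
          es <- if (retrieval == "similarity") {
            new("ExemplarSet",
                positives = .topCandidates(posCand, S, qa, qb, maxK, pol),
                negatives = .topCandidates(negCand, S, qa, qb, maxK, pol),
                k = maxK, metric = config@similarityMetric, query = q)
          } else {
            qseed <- childSeed(seed, paste("rand", f, keys[testIdx[i]]))
            new("ExemplarSet",
                positives = .randomCandidates(posCand, S, qa, qb, maxK, pol,
                                              childSeed(qseed, "rand_pos")),
                negatives = .randomCandidates(negCand, S, qa, qb, maxK, pol,
                                              childSeed(qseed, "rand_neg")),
                k = maxK, metric = "random", query = q)
          }
          exKeys <- c(pairKey(es@positives$id1, es@positives$id2),
                      pairKey(es@negatives$id1, es@negatives$id2))
          if (any(exKeys %in% testKeys))
            stop("leakage: test pair appeared among exemplars")
        }
        for (j in seq_along(ks)) {
          k <- ks[j]
          prompt <- if (k == 0)
            buildZeroShot(q, library, maxChars = config@maxPromptChars)
          else {
            esK <- new("ExemplarSet",
                       positives = utils::head(es@positives, k),
                       negatives = utils::head(es@negatives, k),
                       k = k, metric = es@metric, query = q)
            buildFewShot(q, esK, library, maxChars = config@maxPromptChars)
          }
          preds <- lapply(backends, queryBackend, prompt = prompt)
          sModels <- vapply(preds, slot, numeric(1), "score")
          wUnif <- rep(1 / length(preds), length(preds))
          if (!is.null(judge)) {
            js <- judgePredictions(q, preds, library, judge,
                                   seed = childSeed(seed,
                                                    paste("judge", f, k)))
            w <- deriveWeights(js)
          } else w <- wUnif
          scoreK[i, j] <- sum(w * sModels)
          scoreKUnif[i, j] <- sum(wUnif * sModels)
          if (keepDetails && j == length(ks))
            details[[i]] <- list(pair = q, label = testLabels[i],
                                 s_models = sModels, weights = w)
        }
      }
      list(scoreK = scoreK, scoreKUnif = scoreKUnif, labels = testLabels,
           n = length(testIdx), details = details)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      foldStatus[f] <- paste0("failed: ", conditionMessage(res))
    } else {
      foldStatus[f] <- "ok"
      for (j in seq_along(ks)) {
        perK[[j]][[f]] <- list(
          auc = rocAuc(res$scoreK[, j], res$labels),
          aupr = averagePrecision(res$scoreK[, j], res$labels),
          auc_uniform = rocAuc(res$scoreKUnif[, j], res$labels),
          aupr_uniform = averagePrecision(res$scoreKUnif[, j], res$labels),
          n = res$n, details = res$details)
      }
    }
  }

  mkReport <- function(j) {
    rows <- perK[[j]]
    ok <- which(foldStatus == "ok")
    foldsDf <- data.frame(
      fold = seq_len(folds),
      auc = vapply(seq_len(folds), function(f)
        if (f %in% ok) rows[[f]]$auc else NA_real_, numeric(1)),
      aupr = vapply(seq_len(folds), function(f)
        if (f %in% ok) rows[[f]]$aupr else NA_real_, numeric(1)),
      n_test = vapply(seq_len(folds), function(f)
        if (f %in% ok) rows[[f]]$n else NA_integer_, numeric(1)),
      status = foldStatus, stringsAsFactors = FALSE)
    if (!is.null(judge)) {
      foldsDf$auc_uniform <- vapply(seq_len(folds), function(f)
        if (f %in% ok) rows[[f]]$auc_uniform else NA_real_, numeric(1))
      foldsDf$aupr_uniform <- vapply(seq_len(folds), function(f)
        if (f %in% ok) rows[[f]]$aupr_uniform else NA_real_, numeric(1))
    }
    summary <- c(auc_mean = mean(foldsDf$auc[ok]),
                 auc_sd = stats::sd(foldsDf$auc[ok]),
                 aupr_mean = mean(foldsDf$aupr[ok]),
                 aupr_sd = stats::sd(foldsDf$aupr[ok]))
    cfg <- .configSnapshot(config)
    cfg$k_exemplars <- ks[j]
    cfg$retrieval <- retrieval
    cfg$folds <- folds
    details <- if (keepDetails)
      unlist(lapply(ok, function(f) rows[[f]]$details), recursive = FALSE)
    else list()
    new("EvalReport", folds = foldsDf, summary = summary, config = cfg,
        seed = seed, details = details)
  }
  reports <- lapply(seq_along(ks), mkReport)
  if (singleK) reports[[1]] else
    stats::setNames(reports, paste0("k", ks))
}
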