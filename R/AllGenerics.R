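#' Accessors for core containers
#'
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))
#' @rdname accessors
#' @export
setGeneric("drugSmiles", function(x) standardGeneric("drugSmiles"))
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))
#' @rdname accessors
#' @export
setGeneric("drugTable", function(x) standardGeneric("drugTable"))
#' @rdname accessors
#' @export
setGeneric("interactionPairs", function(x) standardGeneric("interactionPairs"))
#' @rdname accessors
#' @export
setGeneric("nInteractions", function(x) standardGeneric("nInteractions"))

#' @rdname accessors
#' @export
setMethod("drugIds", "DrugLibrary", function(x) x@drugs$id)
#' @rdname accessors
#' @export
setMethod("drugNames", "DrugLibrary",
          function(x) stats::setNames(x@drugs$name, x@drugs$id))
#' @rdname accessors
#' @export
setMethod("drugSmiles", "DrugLibrary",
          function(x) stats::setNames(x@drugs$smiles, x@drugs$id))
#' @rdname accessors
#' @export
setMethod("nDrugs", "DrugLibrary", function(x) nrow(x@drugs))
#' @rdname accessors
#' @export
setMethod("drugTable", "DrugLibrary", function(x) x@drugs)

#' @rdname accessors
#' @export
setMethod("interactionPairs", "InteractionSet", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("nInteractions", "InteractionSet", function(x) nrow(x@pairs))
#' @rdname accessors
#' @export
setMethod("drugIds", "InteractionSet", function(x) drugIds(x@universe))

#' Universe of an InteractionSet
#'
#' @param x an [InteractionSet-class].
#' @return The [DrugLibrary-class] the pairs refer to.
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))
#' @rdname universe
#' @export
setMethod("universe", "InteractionSet", function(x) x@universe)

#' Test membership of an unordered pair
#'
#' @param x an [InteractionSet-class].
#' @param a,b drug ids.
#' @return logical.
#' @export
hasInteraction <- function(x, a, b) {
  pairKey(a, b) %in% pairKey(x@pairs[, 1], x@pairs[, 2])
}

#' Combined exemplar table of an ExemplarSet
#'
#' @param x an [ExemplarSet-class].
#' @param interleave when `TRUE` (default) merge positives and negatives into
#'   one list sorted by globally descending retrieval score — the order in
#'   which few-shot prompts render their example blocks; when `FALSE`, keep
#'   positives first.
#' @return data.frame with columns `id1`, `id2`, `label`, `score`,
#'   `matching`.
#' @export
exemplarTable <- function(x, interleave = TRUE) {
  p <- x@positives; n <- x@negatives
  p$label <- rep("positive", nrow(p)); n$label <- rep("negative", nrow(n))
  out <- rbind(p, n)
  if (interleave && nrow(out)) {
    key <- pairKey(out$id1, out$id2)
    out <- out[order(-out$score, key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[c("id1", "id2", "label", "score", "matching")]
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "DrugLibrary", function(object) {
  cat(sprintf("DrugLibrary with %d drug(s)\n", nDrugs(object)))
  if (nDrugs(object))
    print(utils::head(object@drugs, 4), row.names = FALSE)
  if (nDrugs(object) > 4) cat("  ...\n")
})

setMethod("show", "InteractionSet", function(object) {
  cat(sprintf("InteractionSet: %d interaction(s) over %d drug(s)\n",
              nInteractions(object), nDrugs(object@universe)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat(sprintf("  metric: %s | k: %d | fingerprint: %d bits, radius %d\n",
              object@similarityMetric, object@kExemplars,
              object@fingerprintBits, object@fingerprintRadius))
  cat(sprintf("  WL iterations: %d | leakage: %s | seed: %d\n",
              object@wlIterations, object@leakagePolicy, object@seed))
  cat(sprintf("  backends: %s\n", paste(object@backends, collapse = ", ")))
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d of %d bits set\n",
              length(object@bits), object@nbits))
})

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %d atom(s), %d bond(s) [%s]\n",
              length(object@nodes), nrow(object@edges),
              paste(utils::head(object@nodes, 8), collapse = " ")))
})

setMethod("show", "ExemplarSet", function(object) {
  cat(sprintf(
    "ExemplarSet for query (%s): %d positive, %d negative (k = %d, %s)\n",
    paste(object@query, collapse = ", "), nrow(object@positives),
    nrow(object@negatives), object@k, object@metric))
})

setMethod("show", "Prompt", function(object) {
  cat(sprintf("Prompt [%s], %d section(s), %d characters\n",
              object@kind, length(object@sections), nchar(object@rendered)))
})

setMethod("show", "ModelPrediction", function(object) {
  cat(sprintf("ModelPrediction [%s]: %s (score %.2f)\n",
              object@modelId, object@verdict, object@score))
})

setMethod("show", "FusedPrediction", function(object) {
  cat(sprintf("FusedPrediction (%s): %s, S_final = %.3f over %d model(s)\n",
              paste(object@pair, collapse = ", "), object@verdict,
              object@sFinal, nrow(object@models)))
})

setMethod("show", "EvalReport", function(object) {
  s <- object@summary
  cat(sprintf("EvalReport: %d fold(s)\n", nrow(object@folds)))
  cat(sprintf("  AUC  %.3f +/- %.3f\n", s[["auc_mean"]], s[["auc_sd"]]))
  cat(sprintf("  AUPR %.3f +/- %.3f\n", s[["aupr_mean"]], s[["aupr_sd"]]))
})

setMethod("show", "SyntheticWorld", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticWorld: %d drugs, %d interactions (base_rate %.3g, lambda %.3g, seed %d)\n",
    nDrugs(object@library), nInteractions(object@interactions),
    p$base_rate, p$lambda, p$seed))
})
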