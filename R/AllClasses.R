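#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers
## ---------------------------------------------------------------------------

#' DrugLibrary: a table of drugs with canonical SMILES
#'
#' Holds the drug universe a study operates on: one row per drug with an
#' opaque identifier, a display name and a canonicalized SMILES string.
#' SMILES are canonicalized (Open Babel canonical form) on construction, so
#' two syntactic spellings of the same molecule compare equal downstream.
#'
#' @slot drugs data.frame with columns `id`, `name`, `smiles`; row names are
#'   the ids.
#' @exportClass DrugLibrary
setClass("DrugLibrary", representation(drugs = "data.frame"))

setValidity("DrugLibrary", function(object) {
  d <- object@drugs
  if (!all(c("id", "name", "smiles") %in% names(d)))
    return("drugs must have columns id, name, smiles")
  if (anyDuplicated(d$id))
    return(sprintf("duplicate drug id(s): %s",
                   paste(unique(d$id[duplicated(d$id)]), collapse = ", ")))
  if (nrow(d) > 0 && any(is.na(d$smiles) | !nzchar(d$smiles)))
    return("every drug must carry a non-empty SMILES")
  TRUE
})

#' Construct a DrugLibrary
#'
#' @param id character vector of unique drug identifiers.
#' @param name character vector of display names (defaults to `id`).
#' @param smiles character vector of SMILES strings.
#' @param canonicalize canonicalize SMILES on construction (default `TRUE`).
#'   Construction fails on SMILES that do not parse; use [loadDrugTable()]
#'   for tolerant loading of dirty tables.
#' @return A [DrugLibrary-class] object.
#' @examples
#' lib <- DrugLibrary(c("d1", "d2"), smiles = c("CCO", "c1ccccc1"))
#' nDrugs(lib)
#' @export
DrugLibrary <- function(id, name = id, smiles, canonicalize = TRUE) {
  id <- as.character(id); name <- as.character(name)
  smiles <- as.character(smiles)
  stopifnot(length(id) == length(smiles), length(id) == length(name))
  if (canonicalize && length(smiles)) {
    can <- canonicalizeSmiles(smiles)
    if (anyNA(can))
      stop("invalid SMILES for drug(s): ",
           paste(id[is.na(can)], collapse = ", "))
    smiles <- can
  }
  d <- data.frame(id = id, name = name, smiles = smiles,
                  stringsAsFactors = FALSE)
  d <- d[order(d$id), , drop = FALSE]  # canonical order: loading is
  rownames(d) <- d$id                  # insensitive to input row order
  new("DrugLibrary", drugs = d)
}

#' InteractionSet: known drug-drug interaction edges
#'
#' An unordered, de-duplicated set of interacting drug-id pairs over a
#' [DrugLibrary-class] universe. Pairs are stored with the lexicographically
#' smaller id first, so `(a,b)` and `(b,a)` are the same member and the
#' on-disk representation is canonical.
#'
#' @slot pairs two-column character matrix of drug ids, each row sorted.
#' @slot universe the [DrugLibrary-class] the ids refer to.
#' @exportClass InteractionSet
setClass("InteractionSet",
         representation(pairs = "matrix", universe = "DrugLibrary"))

setValidity("InteractionSet", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (nrow(p)) {
    if (any(p[, 1] == p[, 2])) return("self-pairs are not allowed")
    ids <- object@universe@drugs$id
    unknown <- setdiff(c(p), ids)
    if (length(unknown))
      return(sprintf("pair ids not in library: %s",
                     paste(unknown, collapse = ", ")))
    if (any(p[, 1] > p[, 2])) return("pair rows must be sorted")
    if (anyDuplicated(pairKey(p[, 1], p[, 2])))
      return("duplicate pairs")
  }
  TRUE
})

#' Construct an InteractionSet
#'
#' Self-pairs and duplicates (including order-swapped duplicates) are dropped
#' with a warning naming the count.
#'
#' @param pairs two-column character matrix or data.frame of drug ids.
#' @param universe the [DrugLibrary-class] the ids must belong to.
#' @return An [InteractionSet-class].
#' @examples
#' lib <- DrugLibrary(c("a", "b"), smiles = c("CCO", "CCN"))
#' InteractionSet(rbind(c("a", "b"), c("b", "a")), lib)
#' @export
InteractionSet <- function(pairs, universe) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(character(), 0, 2)
  storage.mode(pairs) <- "character"
  self <- pairs[, 1] == pairs[, 2]
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    pairs <- pairs[!self, , drop = FALSE]
  }
  pairs <- canonicalPairs(pairs)
  key <- pairKey(pairs[, 1], pairs[, 2])
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) dropped")
    pairs <- pairs[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  pairs <- pairs[order(key), , drop = FALSE]
  dimnames(pairs) <- NULL
  new("InteractionSet", pairs = pairs, universe = universe)
}

#' RunConfig: typed configuration for a prediction run
#'
#' Central knobs of the pipeline. Fingerprints default to 2048-bit hashed
#' circular (Morgan-style) fingerprints of radius 2; the Weisfeiler-Lehman
#' kernel runs 3 refinement iterations by default.
#'
#' @slot similarityMetric one of `tanimoto`, `cosine`, `dice`, `graph_wl`,
#'   `embedding`.
#' @slot kExemplars number of positive and of negative in-context exemplars.
#' @slot wlIterations WL refinement iterations (h).
#' @slot fingerprintBits fingerprint length in bits.
#' @slot fingerprintRadius circular-environment radius.
#' @slot seed integer seed governing all randomness of a run.
#' @slot backends character vector naming the backend roster.
#' @slot leakagePolicy `exclude_pair` (drop the query pair from exemplar
#'   candidates) or `exclude_drugs` (drop any candidate sharing a drug with
#'   the query).
#' @slot candidateCap negative-universe subsample cap for hard-negative
#'   mining.
#' @slot decisionThreshold verdict threshold on the fused score.
#' @slot embeddingDim dimension of the default hashing embedding.
#' @slot maxPromptChars rendered-prompt length guard.
#' @exportClass RunConfig
setClass("RunConfig", representation(
  similarityMetric = "character", kExemplars = "integer",
  wlIterations = "integer", fingerprintBits = "integer",
  fingerprintRadius = "integer", seed = "integer", backends = "character",
  leakagePolicy = "character", candidateCap = "integer",
  decisionThreshold = "numeric", embeddingDim = "integer",
  maxPromptChars = "integer"))

.SIM_METRICS <- c("tanimoto", "cosine", "dice", "graph_wl", "embedding")

setValidity("RunConfig", function(object) {
  if (!object@similarityMetric %in% .SIM_METRICS)
    return(sprintf("similarityMetric must be one of %s",
                   paste(.SIM_METRICS, collapse = ", ")))
  if (object@kExemplars < 0) return("kExemplars must be >= 0")
  if (object@wlIterations < 1) return("wlIterations must be >= 1")
  if (object@fingerprintBits < 1) return("fingerprintBits must be positive")
  if (object@fingerprintRadius < 0) return("fingerprintRadius must be >= 0")
  if (!object@leakagePolicy %in% c("exclude_pair", "exclude_drugs"))
    return("leakagePolicy must be exclude_pair or exclude_drugs")
  if (object@candidateCap < 1) return("candidateCap must be positive")
  if (object@decisionThreshold < 0 || object@decisionThreshold > 1)
    return("decisionThreshold must be in [0,1]")
  TRUE
})

#' Create a RunConfig
#'
#' @param similarityMetric,kExemplars,wlIterations,fingerprintBits,
#'   fingerprintRadius,seed,backends,leakagePolicy,candidateCap,
#'   decisionThreshold,embeddingDim,maxPromptChars see [RunConfig-class].
#' @return A validated [RunConfig-class].
#' @examples
#' cfg <- runConfig(kExemplars = 4, seed = 7)
#' @export
runConfig <- function(similarityMetric = "tanimoto", kExemplars = 8,
                      wlIterations = 3, fingerprintBits = 2048,
                      fingerprintRadius = 2, seed = 1,
                      backends = "mock_oracle",
                      leakagePolicy = "exclude_pair", candidateCap = 50000,
                      decisionThreshold = 0.5, embeddingDim = 64,
                      maxPromptChars = 40000) {
  new("RunConfig", similarityMetric = similarityMetric,
      kExemplars = as.integer(kExemplars),
      wlIterations = as.integer(wlIterations),
      fingerprintBits = as.integer(fingerprintBits),
      fingerprintRadius = as.integer(fingerprintRadius),
      seed = as.integer(seed), backends = backends,
      leakagePolicy = leakagePolicy, candidateCap = as.integer(candidateCap),
      decisionThreshold = decisionThreshold,
      embeddingDim = as.integer(embeddingDim),
      maxPromptChars = as.integer(maxPromptChars))
}

## ---------------------------------------------------------------------------
## Molecular representations
## ---------------------------------------------------------------------------

#' Fingerprint: fixed-length binary molecular fingerprint
#'
#' Stored sparsely as the sorted 1-based positions of the on bits.
#'
#' @slot bits sorted integer vector of on-bit positions in `1..nbits`.
#' @slot nbits fingerprint length.
#' @exportClass Fingerprint
setClass("Fingerprint", representation(bits = "integer", nbits = "integer"))

setValidity("Fingerprint", function(object) {
  b <- object@bits
  if (length(b) && (min(b) < 1 || max(b) > object@nbits))
    return("bit positions out of range")
  if (is.unsorted(b, strictly = TRUE)) return("bits must be sorted unique")
  TRUE
})

#' Construct a Fingerprint from on-bit positions or a 0/1 vector
#'
#' @param bits integer vector of on-bit positions (1-based), or, when
#'   `nbits` is missing, a full 0/1 vector whose length defines `nbits`.
#' @param nbits fingerprint length.
#' @return A [Fingerprint-class].
#' @examples
#' fingerprint(c(1, 2, 3), nbits = 8)
#' fingerprint(c(0, 1, 1, 0))
#' @export
fingerprint <- function(bits, nbits) {
  if (missing(nbits)) {
    v <- as.integer(bits)
    stopifnot(all(v %in% c(0L, 1L)))
    return(new("Fingerprint", bits = which(v == 1L), nbits = length(v)))
  }
  new("Fingerprint", bits = sort(unique(as.integer(bits))),
      nbits = as.integer(nbits))
}

#' MolGraph: a heavy-atom molecular graph
#'
#' Nodes are atoms labelled with their element symbol; edges are unordered
#' bonded atom pairs. Bond orders are not retained: the graph kernel reads
#' connectivity and element labels only.
#'
#' @slot nodes character vector of element symbols.
#' @slot edges two-column integer matrix of bonded node indices.
#' @exportClass MolGraph
setClass("MolGraph", representation(nodes = "character", edges = "matrix"))

setValidity("MolGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (min(e) < 1 || max(e) > length(object@nodes))
      return("edge endpoints out of range")
  }
  TRUE
})

#' Construct a MolGraph
#'
#' @param nodes character vector of element symbols.
#' @param edges two-column matrix of bonded node indices (may be empty).
#' @return A [MolGraph-class].
#' @examples
#' molGraph(c("C", "C", "O"), rbind(c(1, 2), c(2, 3)))
#' @export
molGraph <- function(nodes, edges = matrix(integer(), 0, 2)) {
  if (length(edges) == 0) edges <- matrix(integer(), 0, 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  new("MolGraph", nodes = as.character(nodes), edges = edges)
}

## ---------------------------------------------------------------------------
## Retrieval, prompts, predictions
## ---------------------------------------------------------------------------

#' ExemplarSet: in-context exemplars selected for a query pair
#'
#' Top-k most similar known-interacting pairs (positives) and top-k most
#' similar non-interacting pairs (hard negatives), each with its retrieval
#' score and the drug-to-drug matching that achieved it.
#'
#' @slot positives,negatives data.frame with columns `id1`, `id2`, `score`,
#'   `matching`, sorted by descending score.
#' @slot k requested exemplar count per label.
#' @slot metric similarity metric used for retrieval.
#' @slot query the query pair (sorted ids).
#' @exportClass ExemplarSet
setClass("ExemplarSet", representation(
  positives = "data.frame", negatives = "data.frame", k = "integer",
  metric = "character", query = "character"))

setValidity("ExemplarSet", function(object) {
  for (d in list(object@positives, object@negatives)) {
    if (!all(c("id1", "id2", "score", "matching") %in% names(d)))
      return("exemplar frames need columns id1, id2, score, matching")
    if (nrow(d)) {
      if (any(d$score < -1e-12 | d$score > 1 + 1e-12))
        return("scores must lie in [0,1]")
      if (is.unsorted(rev(d$score))) return("scores must be non-increasing")
    }
  }
  TRUE
})

#' Prompt: a rendered, structured LLM prompt
#'
#' @slot kind `zero_shot`, `few_shot` or `judge`.
#' @slot sections named character vector of section bodies in order.
#' @slot rendered the full rendered text.
#' @slot schemaVersion template schema version string.
#' @slot meta list of non-rendered metadata (e.g. the anonymization order of
#'   judge prompts).
#' @exportClass Prompt
setClass("Prompt", representation(
  kind = "character", sections = "character", rendered = "character",
  schemaVersion = "character", meta = "list"))

#' ModelPrediction: one backend's verdict for a query pair
#'
#' @slot modelId backend name.
#' @slot verdict `yes`, `no` or `unparseable`.
#' @slot score numeric interaction score in `[0,1]` (1 = interaction); the
#'   per-model score entering weighted fusion.
#' @slot explanation parsed explanation text.
#' @slot raw full raw response text.
#' @exportClass ModelPrediction
setClass("ModelPrediction", representation(
  modelId = "character", verdict = "character", score = "numeric",
  explanation = "character", raw = "character"))

setValidity("ModelPrediction", function(object) {
  if (!object@verdict %in% c("yes", "no", "unparseable"))
    return("verdict must be yes, no or unparseable")
  s <- object@score
  if (s < 0 || s > 1) return("score must be in [0,1]")
  if (object@verdict == "yes" && s < 0.5) return("yes requires score >= 0.5")
  if (object@verdict == "no" && s > 0.5) return("no requires score <= 0.5")
  if (object@verdict == "unparseable" && s != 0.5)
    return("unparseable requires score 0.5")
  TRUE
})

#' BackendSpec: a pluggable prediction or judge backend
#'
#' The contract is a single handler function mapping a rendered prompt to a
#' raw response text. Mock backends are fully deterministic given their seed;
#' live backends wrap a transport function and retry transient failures.
#'
#' @slot name backend name (used as `modelId`).
#' @slot kind `mock` or `live`.
#' @slot parameters list of backend parameters (`seed`, `p_flip`, `retries`,
#'   ...).
#' @slot handler function(prompt) -> raw response text.
#' @exportClass BackendSpec
setClass("BackendSpec", representation(
  name = "character", kind = "character", parameters = "list",
  handler = "function"))

setValidity("BackendSpec", function(object) {
  if (!object@kind %in% c("mock", "live")) return("kind must be mock or live")
  TRUE
})

#' JudgeScores: rubric scores assigned by the judge
#'
#' One row per model: the four criteria (scientific accuracy, clarity and
#' coherence, evidence support, relevance), each an integer 1..5, and an
#' overall score in `[1,5]` (mean of the criteria when the judge omits it).
#'
#' @slot scores data.frame with columns `model`, `scientific_accuracy`,
#'   `clarity_coherence`, `evidence_support`, `relevance`, `overall`.
#' @exportClass JudgeScores
setClass("JudgeScores", representation(scores = "data.frame"))

.JUDGE_CRITERIA <- c("scientific_accuracy", "clarity_coherence",
                     "evidence_support", "relevance")

setValidity("JudgeScores", function(object) {
  d <- object@scores
  need <- c("model", .JUDGE_CRITERIA, "overall")
  if (!all(need %in% names(d))) return("missing judge score columns")
  for (cr in .JUDGE_CRITERIA) {
    v <- d[[cr]]
    if (any(v < 1 | v > 5 | v != round(v)))
      return(sprintf("criterion %s must be an integer in 1..5", cr))
  }
  if (any(d$overall < 1 | d$overall > 5))
    return("overall must lie in [1,5]")
  TRUE
})

#' FusedPrediction: judge-weighted ensemble verdict for a query pair
#'
#' Holds the fused score `S_final = sum_i w_i * S_model_i`, the weights, the
#' per-model predictions and (when a judge ran) the rubric scores.
#'
#' @slot pair sorted drug-id pair.
#' @slot models data.frame of per-model `model_id`, `verdict`, `score`,
#'   `explanation`.
#' @slot judge data.frame of judge rubric scores (zero rows if no judge).
#' @slot weights numeric weights summing to 1, aligned with `models`.
#' @slot sFinal fused score in `[0,1]`.
#' @slot verdict `yes` or `no`.
#' @exportClass FusedPrediction
setClass("FusedPrediction", representation(
  pair = "character", models = "data.frame", judge = "data.frame",
  weights = "numeric", sFinal = "numeric", verdict = "character"))

setValidity("FusedPrediction", function(object) {
  if (length(object@weights) != nrow(object@models))
    return("one weight per model required")
  if (abs(sum(object@weights) - 1) > 1e-12)
    return("weights must sum to 1")
  s <- object@models$score
  if (length(s) &&
      (object@sFinal < min(s) - 1e-12 || object@sFinal > max(s) + 1e-12))
    return("sFinal must lie within the per-model score range")
  if (!object@verdict %in% c("yes", "no")) return("verdict must be yes or no")
  TRUE
})

## ---------------------------------------------------------------------------
## Evaluation and synthetic worlds
## ---------------------------------------------------------------------------

#' EvalReport: cross-validated AUC/AUPR report
#'
#' @slot folds data.frame with per-fold `fold`, `auc`, `aupr`, `n_test`,
#'   `status`, and per-fold uniform-fusion metrics when a judge ran.
#' @slot summary named numeric vector with mean/sd of AUC and AUPR.
#' @slot config list snapshot of the run configuration.
#' @slot seed the run seed.
#' @slot details optional list of per-query records (kept on request).
#' @exportClass EvalReport
setClass("EvalReport", representation(
  folds = "data.frame", summary = "numeric", config = "list",
  seed = "integer", details = "list"))

#' SyntheticWorld: a generated offline test world
#'
#' A toy molecule library plus a planted interaction structure in which
#' structurally similar drugs tend to share interaction partners (edge
#' probability couples to fingerprint Tanimoto similarity).
#'
#' @slot library the generated [DrugLibrary-class].
#' @slot interactions the planted [InteractionSet-class].
#' @slot latent per-drug latent vectors (n x d matrix).
#' @slot params list of generation parameters (`n_drugs`, `d`, `base_rate`,
#'   `lambda`, `seed`).
#' @exportClass SyntheticWorld
setClass("SyntheticWorld", representation(
  library = "DrugLibrary", interactions = "InteractionSet",
  latent = "matrix", params = "list"))
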