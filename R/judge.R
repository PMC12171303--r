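## Judge-score parsing, weight derivation and weighted fusion of per-model
## predictions into the final ensemble score S_final = sum_i w_i * S_model_i.

.CRITERION_LABELS <- c(scientific_accuracy = "scientific accuracy",
                       clarity_coherence = "clarity and coherence",
                       evidence_support = "evidence support",
                       relevance = "relevance")

#' Parse judge rubric scores from the labelled-lines format
#'
#' The judge prompt mandates one line per entry:
#' `Model <i> - <criterion>: <score>` with the four criteria (scientific
#' accuracy, clarity and coherence, evidence support, relevance) and an
#' optional `overall`. Criterion scores must be integers 1..5; a missing
#' overall defaults to the mean of the four criteria.
#'
#' @param raw judge response text.
#' @param nModels expected number of model blocks; fewer found is a parse
#'   error.
#' @return A [JudgeScores-class] with `model` column `1..nModels`.
#' @export
parseJudgeScores <- function(raw, nModels) {
  stopifnot(nModels >= 1)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  pat <- "^\\s*Model\\s+(\\d+)\\s*[-:–—]\\s*([a-zA-Z ]+?)\\s*:\\s*([0-9.]+)\\s*$"
  hit <- grepl(pat, lines)
  m <- regmatches(lines[hit], regexec(pat, lines[hit]))
  if (length(m) == 0) stop("no judge score lines found")
  idx <- as.integer(vapply(m, `[`, "", 2))
  crit <- tolower(trimws(vapply(m, `[`, "", 3)))
  val <- as.numeric(vapply(m, `[`, "", 4))
  critKey <- names(.CRITERION_LABELS)[match(crit, .CRITERION_LABELS)]
  critKey[crit == "overall"] <- "overall"
  rows <- lapply(seq_len(max(idx)), function(i) {
    sel <- idx == i & !is.na(critKey)
    vals <- stats::setNames(val[sel], critKey[sel])
    missing <- setdiff(names(.CRITERION_LABELS), names(vals))
    if (length(missing))
      stop(sprintf("model %d: missing criterion score(s): %s", i,
                   paste(missing, collapse = ", ")))
    cr <- vals[names(.CRITERION_LABELS)]
    if (any(cr < 1 | cr > 5 | cr != round(cr)))
      stop(sprintf("model %d: criterion score outside 1..5", i))
    ov <- if ("overall" %in% names(vals)) vals[["overall"]] else mean(cr)
    if (ov < 1 || ov > 5)
      stop(sprintf("model %d: overall score outside [1,5]", i))
    c(model = i, cr, overall = ov)
  })
  found <- length(rows)
  if (found < nModels)
    stop(sprintf("judge scored %d model(s), expected %d", found, nModels))
  d <- as.data.frame(do.call(rbind, rows))
  for (cr in names(.CRITERION_LABELS)) d[[cr]] <- as.integer(d[[cr]])
  new("JudgeScores", scores = d)
}

#' Derive fusion weights from judge scores
#'
#' Per-query normalization of the judge's overall scores:
#' `w_i = overall_i / sum_j overall_j`. A fixed-weight override vector can
#' be supplied instead to support rosters with predetermined reliability
#' weights; it is normalized the same way.
#'
#' @param scores a [JudgeScores-class], or a bare numeric vector of overall
#'   scores/fixed weights.
#' @return numeric weights summing to 1.
#' @examples
#' deriveWeights(c(4, 1))
#' @export
deriveWeights <- function(scores) {
  ov <- if (is(scores, "JudgeScores")) scores@scores$overall
        else as.numeric(scores)
  if (length(ov) < 1) stop("at least one model required")
  if (any(ov <= 0)) stop("scores must be positive")
  ov / sum(ov)
}

#' Fuse per-model predictions into the final ensemble prediction
#'
#' Computes `S_final = sum_i w_i * S_model_i` over the per-model scores and
#' thresholds it into the final verdict (`yes` iff `S_final >= threshold`).
#' Weights must be a normalized probability vector, so `S_final` is a convex
#' combination and always lies within the range of the per-model scores.
#'
#' @param predictions list of [ModelPrediction-class].
#' @param weights numeric weights, one per prediction, summing to 1.
#' @param threshold decision threshold on the fused score (default 0.5).
#' @param judge optional [JudgeScores-class] to embed in the record.
#' @param pair optional drug-id pair for the record.
#' @return A [FusedPrediction-class].
#' @examples
#' preds <- list(
#'   new("ModelPrediction", modelId = "a", verdict = "no", score = 0,
#'       explanation = "", raw = "no"),
#'   new("ModelPrediction", modelId = "b", verdict = "yes", score = 1,
#'       explanation = "", raw = "yes"))
#' fusePredictions(preds, c(0.8, 0.2))@sFinal
#' @export
fusePredictions <- function(predictions, weights, threshold = 0.5,
                            judge = NULL, pair = c("drug_a", "drug_b")) {
  if (length(predictions) != length(weights))
    stop("need exactly one weight per prediction")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  s <- vapply(predictions, slot, numeric(1), "score")
  sFinal <- sum(weights * s)
  models <- data.frame(
    model_id = vapply(predictions, slot, "", "modelId"),
    verdict = vapply(predictions, slot, "", "verdict"),
    score = s,
    explanation = vapply(predictions, slot, "", "explanation"),
    stringsAsFactors = FALSE)
  judgeFrame <- if (is.null(judge)) .emptyJudgeFrame() else judge@scores
  new("FusedPrediction", pair = c(min(pair), max(pair)), models = models,
      judge = judgeFrame, weights = weights / sum(weights), sFinal = sFinal,
      verdict = if (sFinal >= threshold) "yes" else "no")
}

#' End-to-end prediction for one query pair
#'
#' Retrieves exemplars (unless `k = 0`), builds the prompt, queries every
#' backend in the roster, optionally judges the responses to derive fusion
#' weights (uniform weights without a judge), and fuses into the final
#' prediction.
#'
#' @param query character vector of two drug ids.
#' @param library a [DrugLibrary-class].
#' @param interactions an [InteractionSet-class] of known interactions the
#'   exemplars may be drawn from.
#' @param backends list of prediction [BackendSpec-class] objects.
#' @param config a [RunConfig-class].
#' @param judge optional judge [BackendSpec-class].
#' @param simMatrix optional precomputed [similarityMatrix()].
#' @param exemplars optional precomputed [ExemplarSet-class] (overrides
#'   retrieval).
#' @return A [FusedPrediction-class].
#' @export
predictPair <- function(query, library, interactions, backends,
                        config = runConfig(), judge = NULL,
                        simMatrix = NULL, exemplars = NULL) {
  if (!is.list(backends)) backends <- list(backends)
  k <- config@kExemplars
  prompt <- if (k == 0) buildZeroShot(query, library,
                                      maxChars = config@maxPromptChars)
  else {
    if (is.null(exemplars))
      exemplars <- buildExemplarSet(query, library, interactions, k, config,
                                    simMatrix)
    buildFewShot(query, exemplars, library,
                 maxChars = config@maxPromptChars)
  }
  preds <- lapply(backends, queryBackend, prompt = prompt)
  judgeScores <- NULL
  weights <- rep(1 / length(preds), length(preds))
  if (!is.null(judge) && length(preds) >= 1) {
    judgeScores <- judgePredictions(query, preds, library, judge,
                                    mode = "zero_shot",
                                    seed = childSeed(config@seed, "judge"))
    weights <- deriveWeights(judgeScores)
  }
  fusePredictions(preds, weights, threshold = config@decisionThreshold,
                  judge = judgeScores, pair = query)
}
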