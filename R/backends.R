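## Backend contract: any source of predictions is a BackendSpec whose
## handler maps a rendered prompt to raw response text. Offline mock
## backends are fully deterministic; live adapters wrap a user-supplied
## transport function and retry transient failures.

#' Parse a free-text yes/no verdict
#'
#' Total function: detects a leading, optionally labelled, case-insensitive
#' yes/no ("Prediction: No", "Answer: yes", bare "No.") at the start of the
#' response; the remainder is the explanation. A response with no detectable
#' verdict maps to `unparseable` with the non-committal score 0.5 and the
#' full text as explanation.
#'
#' @param raw response text.
#' @return list with `verdict` (`yes`/`no`/`unparseable`), `score` (1, 0 or
#'   0.5) and `explanation`.
#' @examples
#' parseVerdict("Answer: yes. Rationale: shared CYP3A4 metabolism.")
#' parseVerdict("The interaction status is unclear.")
#' @export
parseVerdict <- function(raw) {
  stopifnot(length(raw) == 1)
  pat <- paste0("^\\s*(?:(?:final\\s+)?(?:prediction|answer|verdict|",
                "interaction)\\s*[:\\-–—]\\s*)?(yes|no)",
                "(?![a-zA-Z])[.,!:;\\s–—-]*")
  m <- regexpr(pat, raw, perl = TRUE, ignore.case = TRUE)
  if (m == -1)
    return(list(verdict = "unparseable", score = 0.5, explanation = raw))
  verdictTxt <- tolower(regmatches(raw, regexpr("(?i)yes|no", regmatches(raw, m),
                                                perl = TRUE)))
  rest <- trimws(substring(raw, attr(m, "match.length") + 1))
  list(verdict = verdictTxt,
       score = if (verdictTxt == "yes") 1 else 0,
       explanation = rest)
}

#' Construct a live backend specification
#'
#' Thin adapter contract for remote models: `transport` is any function
#' taking the rendered prompt text and returning raw response text (HTTP
#' client, local inference server, ...). Transient transport errors are
#' retried up to `retries` times by [queryBackend()].
#'
#' @param name backend name (becomes the prediction's `modelId`).
#' @param transport function(text) -> raw response text.
#' @param retries number of retries after the first failure (default 2).
#' @param temperature sampling temperature the adapter should request
#'   (default 0 for reproducibility); recorded in the parameters, the
#'   transport is responsible for honouring it.
#' @return A [BackendSpec-class] of kind `live`.
#' @export
liveBackend <- function(name, transport, retries = 2, temperature = 0) {
  new("BackendSpec", name = name, kind = "live",
      parameters = list(retries = as.integer(retries),
                        temperature = temperature),
      handler = transport)
}

#' Obtain a model prediction from a backend
#'
#' Runs the backend's handler on the rendered prompt and parses the raw
#' response into a [ModelPrediction-class]; the raw text is preserved. Live
#' backends retry transient handler failures up to their configured limit
#' and raise a backend-unavailable error carrying the model id when
#' exhausted.
#'
#' @param backend a [BackendSpec-class].
#' @param prompt a [Prompt-class] of kind `zero_shot` or `few_shot`.
#' @return A [ModelPrediction-class].
#' @export
queryBackend <- function(backend, prompt) {
  stopifnot(is(backend, "BackendSpec"), is(prompt, "Prompt"))
  if (!prompt@kind %in% c("zero_shot", "few_shot"))
    stop("prediction backends take zero_shot or few_shot prompts")
  raw <- if (backend@kind == "mock") backend@handler(prompt) else {
    tries <- (backend@parameters$retries %||% 0L) + 1L
    res <- NULL
    for (i in seq_len(tries)) {
      res <- tryCatch(backend@handler(prompt@rendered),
                      error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error"))
      stop(sprintf("backend unavailable after %d attempt(s) [model %s]: %s",
                   tries, backend@name, conditionMessage(res)))
    res
  }
  p <- parseVerdict(raw)
  new("ModelPrediction", modelId = backend@name, verdict = p$verdict,
      score = p$score, explanation = p$explanation, raw = raw)
}

## Extract the query drug names and the top example label from a rendered
## prediction prompt. The input-requirements section precedes the examples,
## so the first two "Drug i:" lines are the query; the first
## "Known interaction:" line belongs to the highest-scoring exemplar.
.parsePredictionPrompt <- function(text) {
  nameA <- sub(".*?Drug 1: (.*?) \\(SMILES:.*", "\\1", text)
  nameB <- sub(".*?Drug 2: (.*?) \\(SMILES:.*", "\\1", text)
  if (identical(nameA, text) || identical(nameB, text))
    stop("prompt is not a recognizable DDI prediction prompt")
  m <- regexpr("Known interaction: (yes|no)", text)
  top <- if (m == -1) NA_character_ else
    sub("Known interaction: ", "", regmatches(text, m), fixed = TRUE)
  list(names = c(nameA, nameB), topLabel = top)
}

#' Deterministic oracle mock backend
#'
#' Offline stand-in for a live model, built around a planted truth so that
#' exemplar quality causally affects accuracy. The mock parses the rendered
#' prompt: with examples present it answers with the label of the
#' highest-scoring exemplar (the first example block), flipped with
#' probability `pFlip`; with no examples (zero-shot) it answers the planted
#' truth flipped with probability `2 * pFlip` — pre-trained knowledge is
#' emulated as a noisier channel than a good demonstration. Flips are a
#' deterministic hash of (backend seed, query, mode), so identical prompts
#' always produce identical predictions and accuracy is monotone in
#' `pFlip`.
#'
#' @param truth an [InteractionSet-class]: the planted ground truth; its
#'   universe maps prompt drug names back to ids.
#' @param pFlip flip probability in `[0, 0.5]`.
#' @param seed backend seed.
#' @param name backend name.
#' @return A [BackendSpec-class] of kind `mock`.
#' @export
oracleMockBackend <- function(truth, pFlip = 0.2, seed = 1,
                              name = "mock_oracle") {
  stopifnot(pFlip >= 0, pFlip <= 0.5)
  lib <- universe(truth)
  idOf <- stats::setNames(drugIds(lib), drugNames(lib))
  handler <- function(prompt) {
    text <- if (is(prompt, "Prompt")) prompt@rendered else prompt
    q <- .parsePredictionPrompt(text)
    if (!all(q$names %in% names(idOf)))
      stop("prompt drug name(s) not in the mock's universe: ",
           paste(setdiff(q$names, names(idOf)), collapse = ", "))
    ids <- sort(unname(idOf[q$names]))
    fewShot <- !is.na(q$topLabel)
    base <- if (fewShot) q$topLabel else
      if (hasInteraction(truth, ids[1], ids[2])) "yes" else "no"
    p <- if (fewShot) pFlip else 2 * pFlip
    u <- hashUnit(paste(name, seed, ids[1], ids[2],
                        if (fewShot) "few" else "zero", sep = ""))
    ans <- if (u < p) setdiff(c("yes", "no"), base) else base
    expl <- if (fewShot)
      paste0("The query pair closely resembles the most similar ",
             "demonstrated pair, whose known interaction status is '",
             q$topLabel, "'; structural similarity of both partners ",
             "suggests the same pharmacological behaviour.")
    else
      paste0("Based on general pharmacological knowledge of the two ",
             "structures, shared metabolic liabilities and receptor ",
             "profiles were weighed against each other.")
    paste0("Answer: ", ans, ". ", expl)
  }
  new("BackendSpec", name = name, kind = "mock",
      parameters = list(p_flip = pFlip, seed = as.integer(seed)),
      handler = handler)
}

#' Synthetic reliability-tracking judge backend
#'
#' Test instrument: a mock judge whose rubric scores track the known
#' reliability of each prediction backend (for the oracle mocks,
#' reliability = 1 - p_flip). The judge prompt's rendered text is fully
#' anonymized; the mock reads the anonymization order from the prompt's
#' `meta` slot, which a live judge would not need. Criterion scores are the
#' rounded overall; the overall maps reliability in `[0.5, 1]` linearly onto
#' `[1, 5]`.
#'
#' @param reliabilities named numeric vector, backend name -> reliability in
#'   `[0.5, 1]`.
#' @param name judge backend name.
#' @return A [BackendSpec-class] of kind `mock` taking judge prompts.
#' @export
mockJudgeBackend <- function(reliabilities, name = "mock_judge") {
  stopifnot(!is.null(names(reliabilities)))
  handler <- function(prompt) {
    stopifnot(is(prompt, "Prompt"), prompt@kind == "judge")
    ord <- prompt@meta$modelOrder
    if (is.null(ord)) stop("judge prompt carries no model order")
    if (!all(ord %in% names(reliabilities)))
      stop("unknown backend(s) in judge prompt: ",
           paste(setdiff(ord, names(reliabilities)), collapse = ", "))
    lines <- unlist(lapply(seq_along(ord), function(i) {
      r <- min(1, max(0.5, reliabilities[[ord[i]]]))
      overall <- 1 + 8 * (r - 0.5)
      crit <- as.integer(min(5, max(1, round(overall))))
      c(sprintf("Model %d - scientific accuracy: %d", i, crit),
        sprintf("Model %d - clarity and coherence: %d", i, crit),
        sprintf("Model %d - evidence support: %d", i, crit),
        sprintf("Model %d - relevance: %d", i, crit),
        sprintf("Model %d - overall: %.2f", i, overall))
    }))
    paste(lines, collapse = "\n")
  }
  new("BackendSpec", name = name, kind = "mock",
      parameters = list(reliabilities = reliabilities), handler = handler)
}

#' Run the judge on a set of predictions
#'
#' Builds the judge prompt, invokes the judge backend and parses the rubric
#' scores back into per-backend order (undoing the anonymization shuffle).
#'
#' @param query character vector of two drug ids.
#' @param predictions list of [ModelPrediction-class].
#' @param library a [DrugLibrary-class].
#' @param judge a judge [BackendSpec-class].
#' @param mode judge prompting mode.
#' @param seed anonymization shuffle seed.
#' @return A [JudgeScores-class] with rows in the order of `predictions`.
#' @export
judgePredictions <- function(query, predictions, library, judge,
                             mode = "zero_shot", seed = 1) {
  prompt <- buildJudgePrompt(query, predictions, library, mode = mode,
                             seed = seed)
  raw <- judge@handler(prompt)
  scores <- parseJudgeScores(raw, length(predictions))
  d <- scores@scores
  d$model <- prompt@meta$modelOrder[match(d$model, seq_along(predictions))]
  want <- vapply(predictions, slot, "", "modelId")
  d <- d[match(want, d$model), , drop = FALSE]
  rownames(d) <- NULL
  new("JudgeScores", scores = d)
}
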