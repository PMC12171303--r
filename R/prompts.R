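## Structured prompt construction. Templates are plain text files with
## {placeholder} slots and "## Section" headers; the template file, not the
## code, is the source of truth for the wording, so users can substitute
## their own phrasing without touching the package.

#' Load a prompt template
#'
#' Templates ship under `inst/templates/` and use `{placeholder}` syntax.
#' Pass `dir` to load user-edited templates from elsewhere.
#'
#' @param kind one of `zero_shot`, `few_shot`, `judge_zero_shot`,
#'   `judge_few_shot`, `example_block`, `judge_model_block`.
#' @param dir optional directory holding `<kind>.txt` files.
#' @return template text (single string).
#' @export
promptTemplate <- local({
  cache <- new.env(parent = emptyenv())
  function(kind, dir = NULL) {
    if (is.null(dir) && !is.null(cache[[kind]])) return(cache[[kind]])
    path <- if (is.null(dir))
      system.file("templates", paste0(kind, ".txt"), package = "ddicl")
    else file.path(dir, paste0(kind, ".txt"))
    if (!nzchar(path) || !file.exists(path))
      stop("no template for kind: ", kind)
    txt <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
    if (is.null(dir)) cache[[kind]] <- txt
    txt
  }
})

#' Render a template by filling its placeholders
#'
#' Every `{name}` slot must be supplied; an unfilled placeholder is an
#' error naming the placeholder.
#'
#' @param template template text.
#' @param values named list/vector of placeholder values.
#' @return rendered text.
#' @export
renderTemplate <- function(template, values) {
  out <- template
  for (nm in names(values))
    out <- gsub(paste0("{", nm, "}"), as.character(values[[nm]]), out,
                fixed = TRUE)
  left <- regmatches(out, gregexpr("\\{[a-zA-Z0-9_]+\\}", out))[[1]]
  if (length(left))
    stop("unfilled placeholder(s): ", paste(unique(left), collapse = ", "))
  out
}

#' Parse the sections of a rendered prompt
#'
#' Inverse of rendering with respect to section structure: splits on
#' `## Section` header lines and returns the named section bodies in order.
#'
#' @param text rendered prompt text (or a [Prompt-class]).
#' @return named character vector of section bodies.
#' @export
parsePromptSections <- function(text) {
  if (is(text, "Prompt")) text <- text@rendered
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr <- grepl("^## ", lines)
  if (!any(hdr)) return(stats::setNames(text, "body"))
  idx <- cumsum(hdr)
  keep <- idx > 0
  nm <- sub("^## ", "", lines[hdr])
  bodies <- vapply(split(lines[keep & !hdr], idx[keep & !hdr]),
                   paste, character(1), collapse = "\n")
  ## sections with no body lines still need a slot
  out <- stats::setNames(character(length(nm)), nm)
  out[as.integer(names(bodies))] <- bodies
  stats::setNames(trimws(out), nm)
}

.newPrompt <- function(kind, rendered, meta = list(), maxChars = 40000) {
  if (nchar(rendered) > maxChars)
    stop(sprintf(
      "rendered prompt is %d characters, exceeding the %d-character guard; reduce k",
      nchar(rendered), maxChars))
  new("Prompt", kind = kind, sections = parsePromptSections(rendered),
      rendered = rendered, schemaVersion = "1.0", meta = meta)
}

.drugFields <- function(library, query) {
  nm <- drugNames(library); sm <- drugSmiles(library)
  if (!all(query %in% names(nm))) stop("drug(s) missing from library: ",
                                       paste(setdiff(query, names(nm)),
                                             collapse = ", "))
  if (any(is.na(sm[query]) | !nzchar(sm[query])))
    stop("missing SMILES for query drug(s)")
  list(name_a = nm[[query[1]]], smiles_a = sm[[query[1]]],
       name_b = nm[[query[2]]], smiles_b = sm[[query[2]]])
}

#' Build a zero-shot prediction prompt
#'
#' Renders the structured prompt (input requirements, prediction task,
#' consideration factors) for a query pair: both drug names and SMILES
#' appear verbatim, the task demands a binary yes/no outcome, and the
#' consideration factors cover pharmacodynamics, metabolic pathways,
#' receptor interactions and clinical data.
#'
#' @param query character vector of two drug ids.
#' @param library a [DrugLibrary-class].
#' @param template optional template text (default: the shipped
#'   `zero_shot` template).
#' @param maxChars rendered-length guard.
#' @return A [Prompt-class] of kind `zero_shot`.
#' @export
buildZeroShot <- function(query, library, template = NULL,
                          maxChars = 40000) {
  template <- template %||% promptTemplate("zero_shot")
  rendered <- renderTemplate(template, .drugFields(library, query))
  .newPrompt("zero_shot", rendered,
             meta = list(query = unname(query)), maxChars = maxChars)
}

#' Build a few-shot prediction prompt
#'
#' Zero-shot sections plus an examples section holding one block per
#' exemplar (names, SMILES and yes/no label). Blocks are ordered by globally
#' descending retrieval score, so the first block is the exemplar most
#' similar to the query.
#'
#' @inheritParams buildZeroShot
#' @param exemplars an [ExemplarSet-class].
#' @param blockTemplate optional example-block template.
#' @return A [Prompt-class] of kind `few_shot`.
#' @export
buildFewShot <- function(query, exemplars, library, template = NULL,
                         blockTemplate = NULL, maxChars = 40000) {
  template <- template %||% promptTemplate("few_shot")
  blockTemplate <- blockTemplate %||% promptTemplate("example_block")
  tab <- exemplarTable(exemplars, interleave = TRUE)
  nm <- drugNames(library); sm <- drugSmiles(library)
  exIds <- unique(c(tab$id1, tab$id2))
  if (!all(exIds %in% names(nm)))
    stop("exemplar drug(s) missing from library: ",
         paste(setdiff(exIds, names(nm)), collapse = ", "))
  blocks <- vapply(seq_len(nrow(tab)), function(i)
    renderTemplate(blockTemplate, list(
      index = i,
      name_a = nm[[tab$id1[i]]], smiles_a = sm[[tab$id1[i]]],
      name_b = nm[[tab$id2[i]]], smiles_b = sm[[tab$id2[i]]],
      label = if (tab$label[i] == "positive") "yes" else "no")),
    character(1))
  vals <- c(.drugFields(library, query),
            list(examples = paste(blocks, collapse = "\n")))
  rendered <- renderTemplate(template, vals)
  .newPrompt("few_shot", rendered,
             meta = list(query = unname(query), n_examples = nrow(tab)),
             maxChars = maxChars)
}

#' Build a judge prompt over multiple model predictions
#'
#' Enumerates each model's verdict and explanation under an anonymized
#' label (Model 1..N) in a seeded-shuffled order, to blunt position and
#' name bias; model names never appear in the rendered text. The prompt
#' instructs 1-5 scoring of the four rubric criteria plus an overall score.
#' `few_shot` mode prepends worked scoring examples.
#'
#' @param query character vector of two drug ids.
#' @param predictions list of [ModelPrediction-class] objects (at least 1).
#' @param library a [DrugLibrary-class].
#' @param mode `zero_shot` or `few_shot` judging.
#' @param seed seed for the anonymization shuffle.
#' @param template,blockTemplate optional template overrides.
#' @param maxChars rendered-length guard.
#' @return A [Prompt-class] of kind `judge`; the anonymization order (model
#'   ids in block order) is carried in `meta$modelOrder`, not in the text.
#' @export
buildJudgePrompt <- function(query, predictions, library,
                             mode = c("zero_shot", "few_shot"), seed = 1,
                             template = NULL, blockTemplate = NULL,
                             maxChars = 40000) {
  mode <- match.arg(mode)
  if (length(predictions) == 0) stop("at least one prediction required")
  template <- template %||%
    promptTemplate(paste0("judge_", mode))
  blockTemplate <- blockTemplate %||% promptTemplate("judge_model_block")
  ord <- withSeed(childSeed(seed, "judge_shuffle"),
                  sample.int(length(predictions)))
  shuffled <- predictions[ord]
  blocks <- vapply(seq_along(shuffled), function(i)
    renderTemplate(blockTemplate, list(
      index = i, verdict = shuffled[[i]]@verdict,
      explanation = shuffled[[i]]@explanation)),
    character(1))
  vals <- c(.drugFields(library, query),
            list(n_models = length(predictions),
                 model_blocks = paste(blocks, collapse = "\n")))
  rendered <- renderTemplate(template, vals)
  .newPrompt("judge", rendered,
             meta = list(query = unname(query), mode = mode,
                         modelOrder = vapply(shuffled, slot, "", "modelId")),
             maxChars = maxChars)
}
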