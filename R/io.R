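## On-disk artifacts: drug tables (CSV/TSV/.smi), interaction edge lists
## (TSV), prediction records (JSON lines), evaluation reports (JSON) and run
## configuration (YAML).

#' Load a drug table
#'
#' Reads a drug table with columns `id`, `name`, `smiles` (CSV or TSV), or a
#' `.smi` file with one `SMILES<whitespace>id` per line (name taken from the
#' id). SMILES are canonicalized; rows whose SMILES do not parse are skipped
#' with a warning naming the offending line numbers, unless `strict = TRUE`,
#' in which case loading aborts. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param format `csv`, `tsv` or `smi`; guessed from the file extension by
#'   default.
#' @param strict abort on the first invalid SMILES instead of skipping.
#' @return A [DrugLibrary-class].
#' @export
loadDrugTable <- function(path, format = c("auto", "csv", "tsv", "smi"),
                          strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", smi = "smi",
                     stop("cannot guess format from extension: ", ext))
  }
  if (format == "smi") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    toks <- strsplit(trimws(lines[keep]), "\\s+")
    if (any(lengths(toks) < 2))
      stop("format error: .smi lines must be 'SMILES<whitespace>id'")
    d <- data.frame(id = vapply(toks, `[`, "", 2),
                    smiles = vapply(toks, `[`, "", 1),
                    stringsAsFactors = FALSE)
    d$name <- d$id
    lineNo <- which(keep)
  } else {
    sep <- if (format == "csv") "," else "\t"
    ## strip full-line # headers only: '#' is a SMILES bond symbol, so it
    ## must not act as an in-line comment character
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines)
    d <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
    missing <- setdiff(c("id", "name", "smiles"), names(d))
    if (length(missing))
      stop("format error: missing column(s): ",
           paste(missing, collapse = ", "))
    lineNo <- which(keep)[-1]  # line numbers in the file, minus the header
  }
  if (anyDuplicated(d$id))
    stop("duplicate drug id(s): ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  can <- canonicalizeSmiles(d$smiles)
  bad <- is.na(can)
  if (any(bad)) {
    msg <- sprintf("invalid SMILES on line(s) %s (id: %s)",
                   paste(lineNo[bad], collapse = ", "),
                   paste(d$id[bad], collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; row(s) skipped")
  }
  d <- d[!bad, , drop = FALSE]; can <- can[!bad]
  if (nrow(d) == 0) stop("empty input: no valid drug rows in ", path)
  DrugLibrary(d$id, d$name, can, canonicalize = FALSE)
}

#' Load an interaction edge list
#'
#' Reads a two-column TSV of drug ids (lines starting with `#` ignored) and
#' returns the unordered, de-duplicated interaction set; dropped duplicates
#' and self-pairs are reported by warning. Loading is order-insensitive.
#'
#' @param path file path.
#' @param library the [DrugLibrary-class] the ids must belong to.
#' @return An [InteractionSet-class].
#' @export
loadInteractionList <- function(path, library) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  if (!any(keep)) {
    warning("empty interaction list: ", path)
    return(InteractionSet(matrix(character(), 0, 2), library))
  }
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  if (any(lengths(toks) < 2))
    stop("format error: interaction lines must carry two drug ids")
  pairs <- cbind(vapply(toks, `[`, "", 1), vapply(toks, `[`, "", 2))
  ids <- drugIds(library)
  unknown <- !(pairs[, 1] %in% ids & pairs[, 2] %in% ids)
  if (any(unknown)) {
    i <- which(unknown)[1]
    badId <- setdiff(c(pairs[i, ]), ids)[1]
    stop(sprintf("unknown drug id '%s' on line %d", badId,
                 which(keep)[i]))
  }
  InteractionSet(pairs, library)
}

## ---------------------------------------------------------------------------
## Prediction records (JSON lines)
## ---------------------------------------------------------------------------

.fusedToList <- function(x) {
  list(pair = x@pair,
       models = x@models,
       judge = x@judge,
       weights = x@weights,
       s_final = x@sFinal,
       verdict = x@verdict)
}

.fusedFromList <- function(l) {
  models <- as.data.frame(l$models, stringsAsFactors = FALSE)
  judge <- if (length(l$judge)) as.data.frame(l$judge) else
    .emptyJudgeFrame()
  new("FusedPrediction", pair = unlist(l$pair),
      models = models[c("model_id", "verdict", "score", "explanation")],
      judge = judge, weights = as.numeric(unlist(l$weights)),
      sFinal = as.numeric(l$s_final), verdict = l$verdict)
}

.emptyJudgeFrame <- function() {
  d <- data.frame(model = character(), scientific_accuracy = integer(),
                  clarity_coherence = integer(), evidence_support = integer(),
                  relevance = integer(), overall = numeric(),
                  stringsAsFactors = FALSE)
  d
}

#' Write fused prediction records as JSON lines
#'
#' One structured record per line: pair ids, per-model verdicts, scores and
#' explanations, judge scores, weights, the fused score and the final
#' verdict. `readPredictions(writePredictions(x)) == x` holds, including for
#' non-ASCII explanation text (files are UTF-8).
#'
#' @param records list of [FusedPrediction-class] objects (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(.fusedToList(r), auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Read fused prediction records from a JSON-lines file
#'
#' @param path file written by [writePredictions()].
#' @return list of [FusedPrediction-class] objects.
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) .fusedFromList(jsonlite::fromJSON(l)))
}

## ---------------------------------------------------------------------------
## Run configuration (YAML)
## ---------------------------------------------------------------------------

.CONFIG_KEYS <- c(similarity_metric = "similarityMetric",
                  k_exemplars = "kExemplars", wl_iterations = "wlIterations",
                  fingerprint_bits = "fingerprintBits",
                  fingerprint_radius = "fingerprintRadius", seed = "seed",
                  backends = "backends", leakage_policy = "leakagePolicy",
                  candidate_cap = "candidateCap",
                  decision_threshold = "decisionThreshold",
                  embedding_dim = "embeddingDim",
                  max_prompt_chars = "maxPromptChars")

#' Read a run configuration from YAML
#'
#' Flat, typed key-value file using snake_case keys (`similarity_metric`,
#' `k_exemplars`, ...). Unknown keys are rejected: a silently ignored typo in
#' `k_exemplars` would invalidate an experiment.
#'
#' @param path YAML file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(.CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$backends)) vals$backends <- unlist(vals$backends)
  args <- stats::setNames(vals, .CONFIG_KEYS[names(vals)])
  do.call(runConfig, args)
}

#' Write a run configuration to YAML
#'
#' @param config a [RunConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  vals <- lapply(.CONFIG_KEYS, function(sl) slot(config, sl))
  yaml::write_yaml(vals, path)
  invisible(path)
}

## Plain-list snapshot of a config (embedded in reports).
.configSnapshot <- function(config) {
  lapply(stats::setNames(nm = names(.CONFIG_KEYS)),
         function(k) slot(config, .CONFIG_KEYS[[k]]))
}

## ---------------------------------------------------------------------------
## Evaluation reports (JSON)
## ---------------------------------------------------------------------------

#' Write an evaluation report to JSON
#'
#' @param report an [EvalReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  obj <- list(schema_version = "1.0",
              seed = report@seed,
              config = report@config,
              folds = report@folds,
              summary = as.list(report@summary))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             path)
  invisible(path)
}

#' Read an evaluation report written by [writeEvalReport()]
#'
#' @param path JSON file path.
#' @return An [EvalReport-class].
#' @export
readEvalReport <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new("EvalReport", folds = as.data.frame(obj$folds),
      summary = unlist(obj$summary), config = as.list(obj$config),
      seed = as.integer(obj$seed), details = list())
}
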