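test_that("zero-shot prompts carry the query verbatim with fixed sections", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  p <- buildZeroShot(q, w@library)
  expect_s4_class(p, "Prompt")
  expect_equal(p@kind, "zero_shot")
  expect_equal(names(p@sections),
               c("Input requirements", "Prediction task",
                 "Consideration factors"))
  sm <- drugSmiles(w@library)
  input <- p@sections[["Input requirements"]]
  for (id in q) {
    hits <- gregexpr(sm[[id]], input, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), 1)  # SMILES exactly once in the input
    expect_match(input, drugNames(w@library)[[id]], fixed = TRUE)
  }
  expect_match(p@rendered, "\"yes\" or \"no\"", fixed = TRUE)
  for (factor in c("pharmacodynamics", "metabolic", "receptor", "clinical"))
    expect_match(tolower(p@rendered), factor)
  ## determinism: identical bytes
  expect_identical(p@rendered, buildZeroShot(q, w@library)@rendered)
})

test_that("template rendering fails loudly on unfilled placeholders", {
  expect_error(renderTemplate("Drug: {name_a} ({smiles_a})",
                              list(name_a = "x")),
               "\\{smiles_a\\}")
  expect_error(buildZeroShot(sort(interactionPairs(tinyWorld()@interactions)[1, ]),
                             tinyWorld()@library,
                             template = "{name_a} {name_b} {oops}"),
               "\\{oops\\}")
})

test_that("few-shot prompts render one block per exemplar in score order", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[1, ])
  es <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
  p <- buildFewShot(q, es, w@library)
  expect_equal(p@kind, "few_shot")
  blocks <- gregexpr("Example [0-9]+:", p@rendered)[[1]]
  expect_length(blocks, 4)  # k positives + k negatives
  ## labels map positive -> yes, negative -> no, in interleaved score order
  tab <- exemplarTable(es)
  labs <- regmatches(p@rendered,
                     gregexpr("Known interaction: (yes|no)", p@rendered))[[1]]
  expect_equal(sub("Known interaction: ", "", labs),
               ifelse(tab$label == "positive", "yes", "no"))
  ## the first block is the highest-scoring exemplar
  expect_equal(tab$score, sort(tab$score, decreasing = TRUE))
})

test_that("an empty exemplar set reduces a few-shot prompt to the zero-shot sections", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  empty <- new("ExemplarSet",
               positives = data.frame(id1 = character(), id2 = character(),
                                      score = numeric(),
                                      matching = character()),
               negatives = data.frame(id1 = character(), id2 = character(),
                                      score = numeric(),
                                      matching = character()),
               k = 0L, metric = "tanimoto", query = q)
  pf <- buildFewShot(q, empty, w@library)
  pz <- buildZeroShot(q, w@library)
  expect_equal(pf@sections[names(pz@sections)], pz@sections)
  expect_false(grepl("Example [0-9]+:", pf@rendered))
})

test_that("prompt sections round-trip through the section parser", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[2, ])
  es <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
  p <- buildFewShot(q, es, w@library)
  reparsed <- parsePromptSections(p@rendered)
  expect_identical(reparsed, p@sections)
})

test_that("the prompt length guard rejects oversized renderings", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  expect_error(buildZeroShot(q, w@library, maxChars = 50),
               "exceeding")
})

test_that("judge prompts anonymize models and gate worked examples by mode", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  preds <- lapply(c("alpha_model", "beta_model", "gamma_model"), function(m)
    new("ModelPrediction", modelId = m, verdict = "yes", score = 1,
        explanation = paste("reasoning from", "shared pathways"),
        raw = "Answer: yes."))
  pj <- buildJudgePrompt(q, preds, w@library, mode = "zero_shot", seed = 4)
  expect_equal(pj@kind, "judge")
  expect_length(gregexpr("Model [0-9]+:", pj@rendered)[[1]], 3)
  for (m in c("alpha_model", "beta_model", "gamma_model"))
    expect_false(grepl(m, pj@rendered, fixed = TRUE))
  expect_setequal(pj@meta$modelOrder,
                  c("alpha_model", "beta_model", "gamma_model"))
  expect_false(grepl("Worked scoring examples", pj@rendered))
  pj2 <- buildJudgePrompt(q, preds, w@library, mode = "few_shot", seed = 4)
  expect_match(pj2@rendered, "Worked scoring examples")
  ## deterministic shuffle
  expect_identical(pj@rendered,
                   buildJudgePrompt(q, preds, w@library, seed = 4)@rendered)
  expect_error(buildJudgePrompt(q, list(), w@library), "at least one")
})
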