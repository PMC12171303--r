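judgeText <- function(models) {
  ## models: list of named vectors with the four criteria (+ optional overall)
  unlist(lapply(seq_along(models), function(i) {
    m <- models[[i]]
    lines <- c(sprintf("Model %d - scientific accuracy: %s", i, m[["sa"]]),
               sprintf("Model %d - clarity and coherence: %s", i, m[["cc"]]),
               sprintf("Model %d - evidence support: %s", i, m[["es"]]),
               sprintf("Model %d - relevance: %s", i, m[["re"]]))
    if (!is.na(m["ov"]))
      lines <- c(lines, sprintf("Model %d - overall: %s", i, m[["ov"]]))
    lines
  }))
}

test_that("judge scores parse from the labelled-lines format", {
  raw <- paste(judgeText(list(c(sa = 5, cc = 4, es = 3, re = 5, ov = 4.5),
                              c(sa = 2, cc = 3, es = 1, re = 2, ov = 2))),
               collapse = "\n")
  js <- parseJudgeScores(raw, 2)
  expect_equal(nrow(js@scores), 2)
  expect_equal(js@scores$scientific_accuracy, c(5L, 2L))
  expect_equal(js@scores$overall, c(4.5, 2))
})

test_that("a missing overall defaults to the mean of the four criteria", {
  raw <- paste(judgeText(list(c(sa = 5, cc = 5, es = 5, re = 5, ov = NA))),
               collapse = "\n")
  js <- parseJudgeScores(raw, 1)
  expect_equal(js@scores$overall, 5)
  raw2 <- paste(judgeText(list(c(sa = 4, cc = 3, es = 2, re = 1, ov = NA))),
                collapse = "\n")
  expect_equal(parseJudgeScores(raw2, 1)@scores$overall, 2.5)
})

test_that("judge score parsing validates ranges and completeness", {
  bad <- paste(judgeText(list(c(sa = 0, cc = 3, es = 3, re = 3, ov = NA))),
               collapse = "\n")
  expect_error(parseJudgeScores(bad, 1), "outside 1\\.\\.5")
  missing <- "Model 1 - scientific accuracy: 4\nModel 1 - relevance: 4"
  expect_error(parseJudgeScores(missing, 1), "missing criterion")
  one <- paste(judgeText(list(c(sa = 4, cc = 4, es = 4, re = 4, ov = 4))),
               collapse = "\n")
  expect_error(parseJudgeScores(one, 2), "scored 1 model")
  expect_error(parseJudgeScores("nothing to see", 1), "no judge score")
})

test_that("weights normalize judge overall scores", {
  expect_equal(deriveWeights(c(4, 1)), c(0.8, 0.2))
  expect_equal(deriveWeights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(deriveWeights(5), 1)
  raw <- paste(judgeText(list(c(sa = 4, cc = 4, es = 4, re = 4, ov = 4),
                              c(sa = 1, cc = 1, es = 1, re = 1, ov = 1))),
               collapse = "\n")
  expect_equal(deriveWeights(parseJudgeScores(raw, 2)), c(0.8, 0.2))
  expect_error(deriveWeights(numeric()), "at least one")
})

mkPred <- function(id, score) {
  v <- if (score >= 0.5) "yes" else "no"
  if (score == 0.5) v <- "unparseable"
  new("ModelPrediction", modelId = id, verdict = v, score = score,
      explanation = paste("because", id), raw = paste0("Answer: ", v))
}

test_that("fusion reproduces hand-computed weighted sums and verdicts", {
  f <- fusePredictions(list(mkPred("a", 0), mkPred("b", 1)), c(0.8, 0.2))
  expect_equal(f@sFinal, 0.2)
  expect_equal(f@verdict, "no")
  f2 <- fusePredictions(list(mkPred("a", 1), mkPred("b", 0), mkPred("c", 1)),
                        rep(1 / 3, 3))
  expect_equal(f2@sFinal, 2 / 3)
  expect_equal(f2@verdict, "yes")
  expect_error(fusePredictions(list(mkPred("a", 1)), c(0.5, 0.5)),
               "one weight per prediction")
  expect_error(fusePredictions(list(mkPred("a", 1)), 0.7), "sum to 1")
})

test_that("fusion is convex, permutation-equivariant and mean-reducing", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    scores <- round(stats::runif(n), 3)
    preds <- lapply(seq_len(n), function(j) {
      s <- scores[j]
      v <- if (s > 0.5) "yes" else if (s < 0.5) "no" else "unparseable"
      new("ModelPrediction", modelId = paste0("m", j), verdict = v,
          score = s, explanation = "", raw = "")
    })
    w <- stats::runif(n); w <- w / sum(w)
    f <- fusePredictions(preds, w)
    expect_gte(f@sFinal, min(scores) - 1e-12)
    expect_lte(f@sFinal, max(scores) + 1e-12)
    expect_equal(sum(f@weights), 1)
    perm <- sample.int(n)
    expect_equal(fusePredictions(preds[perm], w[perm])@sFinal, f@sFinal)
    ## degenerate judge: equal weights = arithmetic mean
    expect_equal(fusePredictions(preds, rep(1 / n, n))@sFinal, mean(scores))
    ## identical scores: any weights return the common value
    same <- lapply(preds, function(p) { p@score <- 0.7; p@verdict <- "yes"; p })
    expect_equal(fusePredictions(same, w)@sFinal, 0.7)
  }
})

test_that("the judge pipeline maps anonymized scores back to backends", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  preds <- list(mkPred("backend_one", 1), mkPred("backend_two", 0),
                mkPred("backend_three", 1))
  rel <- c(backend_one = 0.95, backend_two = 0.7, backend_three = 0.55)
  judge <- mockJudgeBackend(rel)
  for (seed in c(1, 2, 9)) {  # different anonymization shuffles
    js <- judgePredictions(q, preds, w@library, judge, seed = seed)
    expect_equal(js@scores$model,
                 c("backend_one", "backend_two", "backend_three"))
    ## higher reliability always yields a higher overall
    expect_true(all(diff(js@scores$overall) < 0))
  }
  js <- judgePredictions(q, preds, w@library, judge, seed = 1)
  wts <- deriveWeights(js)
  expect_equal(sum(wts), 1)
  expect_true(wts[1] > wts[2] && wts[2] > wts[3])
})
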