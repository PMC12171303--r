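test_that("verdict parsing is total and handles labelled, bare and missing verdicts", {
  p1 <- parseVerdict("Answer: yes. Rationale: shared CYP3A4 metabolism.")
  expect_equal(p1$verdict, "yes")
  expect_equal(p1$score, 1)
  expect_equal(p1$explanation, "Rationale: shared CYP3A4 metabolism.")

  expect_equal(parseVerdict("no")[c("verdict", "score", "explanation")],
               list(verdict = "no", score = 0, explanation = ""))
  expect_equal(parseVerdict("Prediction: No")$verdict, "no")
  expect_equal(parseVerdict("  VERDICT - Yes, clearly.")$verdict, "yes")
  expect_equal(parseVerdict("Yes — these drugs interact because of QT risk")$verdict,
               "yes")

  p2 <- parseVerdict("The interaction status is unclear.")
  expect_equal(p2$verdict, "unparseable")
  expect_equal(p2$score, 0.5)
  expect_equal(p2$explanation, "The interaction status is unclear.")
  ## "no" must not fire inside a longer word
  expect_equal(parseVerdict("Notable overlap exists")$verdict, "unparseable")
})

test_that("verdict parsing is idempotent on its own explanation output", {
  raws <- c("Answer: yes. Strong mechanistic overlap.",
            "Prediction: no — distinct metabolic routes.",
            "Insufficient evidence either way.",
            "no")
  for (r in raws) {
    first <- parseVerdict(r)
    second <- parseVerdict(first$explanation)
    expect_equal(second$explanation,
                 parseVerdict(second$explanation)$explanation)
  }
})

test_that("mock backends are deterministic and live backends retry then fail", {
  w <- tinyWorld()
  q <- sort(interactionPairs(w@interactions)[1, ])
  prompt <- buildZeroShot(q, w@library)
  b <- oracleMockBackend(w@interactions, pFlip = 0.3, seed = 2)
  p1 <- queryBackend(b, prompt)
  p2 <- queryBackend(b, prompt)
  expect_identical(p1@raw, p2@raw)
  expect_identical(p1@verdict, p2@verdict)
  ## two mocks with the same seed produce identical streams
  b2 <- oracleMockBackend(w@interactions, pFlip = 0.3, seed = 2)
  expect_identical(queryBackend(b2, prompt)@raw, p1@raw)

  dead <- liveBackend("remote_x", function(text) stop("connection refused"),
                      retries = 0)
  expect_error(queryBackend(dead, prompt), "backend unavailable.*remote_x")
  ## transient failure is retried
  n <- 0
  flaky <- liveBackend("remote_y", function(text) {
    n <<- n + 1
    if (n < 3) stop("timeout") else "Answer: no. Nothing shared."
  }, retries = 2)
  expect_equal(queryBackend(flaky, prompt)@verdict, "no")
  ## prediction backends reject judge prompts
  pj <- buildJudgePrompt(q, list(p1), w@library)
  expect_error(queryBackend(b, pj), "zero_shot or few_shot")
})

test_that("the noiseless oracle mock echoes the top exemplar label few-shot and the truth zero-shot", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  b0 <- oracleMockBackend(w@interactions, pFlip = 0, seed = 1)
  pos <- interactionPairs(w@interactions)
  for (i in seq_len(min(6, nrow(pos)))) {
    q <- sort(pos[i, ])
    es <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
    fs <- queryBackend(b0, buildFewShot(q, es, w@library))
    top <- exemplarTable(es)$label[1]
    expect_equal(fs@verdict, if (top == "positive") "yes" else "no")
    zs <- queryBackend(b0, buildZeroShot(q, w@library))
    expect_equal(zs@verdict, "yes")  # true edges, zero flip probability
  }
})

test_that("mock accuracy tracks 2*p_flip zero-shot and is monotone in p_flip", {
  w <- memoFixture("backendWorld",
                   generateWorld(nDrugs = 40, baseRate = 0.15, lambda = 4,
                                 seed = 8))
  pos <- interactionPairs(w@interactions)
  negU <- ddicl:::.negativeUniverse(w@library, w@interactions)
  set.seed(31)
  nPos <- min(nrow(pos), 250)
  queries <- rbind(pos[sample.int(nrow(pos), nPos), ],
                   negU[sample.int(nrow(negU), 250), ])
  truths <- rep(c("yes", "no"), c(nPos, 250))
  prompts <- lapply(seq_len(nrow(queries)), function(i)
    buildZeroShot(sort(queries[i, ]), w@library))
  acc <- function(pFlip) {
    b <- oracleMockBackend(w@interactions, pFlip = pFlip, seed = 5)
    mean(vapply(seq_along(prompts), function(i)
      queryBackend(b, prompts[[i]])@verdict == truths[i], logical(1)))
  }
  accs <- vapply(c(0, 0.1, 0.3, 0.5), acc, numeric(1))
  n <- length(prompts)
  expect_equal(accs[1], 1)               # noiseless
  ## p_flip = 0.5: zero-shot flips with probability 1 -> accuracy 0
  expect_equal(accs[4], 0)
  ## monotone non-increasing in p_flip
  expect_true(all(diff(accs) <= 0))
  ## p_flip = 0.1 flips 20%: binomial check
  expect_lt(abs(accs[2] - 0.8), 4 * sqrt(0.8 * 0.2 / n))
})

test_that("few-shot mock accuracy is approximately 1 - p_flip against the exemplar label", {
  w <- memoFixture("backendWorld",
                   generateWorld(nDrugs = 40, baseRate = 0.15, lambda = 4,
                                 seed = 8))
  cfg <- runConfig(kExemplars = 2, seed = 3)
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  pos <- interactionPairs(w@interactions)
  set.seed(17)
  take <- sample.int(nrow(pos), 300, replace = TRUE)
  prompts <- list(); tops <- character(length(take))
  for (j in seq_along(take)) {
    q <- sort(pos[take[j], ])
    es <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
    tops[j] <- if (exemplarTable(es)$label[1] == "positive") "yes" else "no"
    prompts[[j]] <- buildFewShot(q, es, w@library)
  }
  b <- oracleMockBackend(w@interactions, pFlip = 0.25, seed = 13)
  agree <- mean(vapply(seq_along(prompts), function(j)
    queryBackend(b, prompts[[j]])@verdict == tops[j], logical(1)))
  expect_lt(abs(agree - 0.75), 4 * sqrt(0.75 * 0.25 / 300))
})
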