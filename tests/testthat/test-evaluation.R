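test_that("AUC matches closed-form cases and rejects single-class input", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "at least one")
})

test_that("AUC equals the brute-force pair comparison, including ties", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(rocAuc(scores, labels), bruteForceAuc(scores, labels))
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- runif(n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(scores, labels), ref)
  }
})

test_that("average precision matches closed forms and the brute-force oracle", {
  expect_equal(averagePrecision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  ## single positive ranked last of n: precision 1/n at its recall step
  for (n in c(4, 7, 12)) {
    scores <- seq(1, 0.1, length.out = n)
    labels <- c(rep(0, n - 1), 1)
    expect_equal(averagePrecision(scores, labels), 1 / n)
  }
  expect_error(averagePrecision(c(0.3, 0.2), c(0, 0)), "no positive")
  set.seed(91)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.4))
    scores <- round(runif(n), 1)
    expect_equal(averagePrecision(scores, labels),
                 bruteForceAp(scores, labels))
  }
})

test_that("k-fold splits partition, stratify and reproduce", {
  labels <- rep(c(1, 0), each = 50)
  sp <- kfoldSplit(labels, folds = 10, seed = 4)
  tests <- lapply(sp, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)       # exact partition
  for (f in seq_along(sp)) {
    expect_equal(length(tests[[f]]), 10)
    expect_lte(abs(sum(labels[tests[[f]]]) - 5), 1)  # stratified 5/5 +- 1
    expect_equal(sort(c(sp[[f]]$train, sp[[f]]$test)), 1:100)
  }
  expect_identical(kfoldSplit(labels, 10, seed = 4), sp)
  expect_false(identical(kfoldSplit(labels, 10, seed = 5), sp))
  expect_error(kfoldSplit(rep(1, 5), folds = 10), "too few")
})

test_that("zero-shot cross-validation with a noiseless oracle is perfect", {
  w <- tinyWorld()
  cfg <- runConfig(kExemplars = 0, seed = 6)
  b <- oracleMockBackend(w@interactions, pFlip = 0, seed = 6)
  rep <- runCV(w@library, w@interactions, list(b), cfg, folds = 3)
  expect_equal(rep@folds$status, rep("ok", 3))
  ## zero-shot, p_flip = 0: the mock answers the planted truth exactly
  expect_equal(rep@folds$auc, rep(1, 3))
  expect_equal(rep@summary[["auc_mean"]], 1)
  expect_equal(rep@config$k_exemplars, 0L)
})

test_that("cross-validation is deterministic end to end", {
  w <- tinyWorld()
  cfg <- runConfig(kExemplars = 2, seed = 9)
  b <- oracleMockBackend(w@interactions, pFlip = 0.2, seed = 9)
  r1 <- runCV(w@library, w@interactions, list(b), cfg, folds = 3)
  r2 <- runCV(w@library, w@interactions, list(b), cfg, folds = 3)
  expect_identical(r1@folds, r2@folds)
  expect_identical(r1@summary, r2@summary)
})

test_that("exemplars never leak fold test pairs and reports carry fold structure", {
  w <- memoFixture("cvWorld",
                   generateWorld(nDrugs = 60, baseRate = 0.08, lambda = 4,
                                 seed = 12))
  cfg <- runConfig(kExemplars = 3, seed = 12)
  b <- oracleMockBackend(w@interactions, pFlip = 0.1, seed = 12)
  rep <- runCV(w@library, w@interactions, list(b), cfg, folds = 5,
               keepDetails = TRUE)
  ## the leakage assertion inside run_cv aborts a fold on violation, so a
  ## clean status on every fold certifies train/test separation
  expect_equal(rep@folds$status, rep("ok", 5))
  expect_equal(sum(rep@folds$n_test), 2 * nInteractions(w@interactions))
  expect_true(all(rep@folds$auc >= 0 & rep@folds$auc <= 1))
  expect_length(rep@details, sum(rep@folds$n_test))
})

test_that("a k sweep shares retrieval and equals single-k runs", {
  w <- memoFixture("cvWorld",
                   generateWorld(nDrugs = 60, baseRate = 0.08, lambda = 4,
                                 seed = 12))
  cfg <- runConfig(kExemplars = 2, seed = 12)
  b <- oracleMockBackend(w@interactions, pFlip = 0.2, seed = 12)
  sweep <- runCV(w@library, w@interactions, list(b), cfg, folds = 3,
                 ks = c(0, 2))
  single0 <- runCV(w@library, w@interactions, list(b),
                   runConfig(kExemplars = 0, seed = 12), folds = 3)
  expect_equal(sweep$k0@folds$auc, single0@folds$auc)
  single2 <- runCV(w@library, w@interactions, list(b), cfg, folds = 3)
  expect_equal(sweep$k2@folds$auc, single2@folds$auc)
})
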