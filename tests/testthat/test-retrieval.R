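test_that("pair similarity takes the better of the two assignments", {
  ## custom similarity matrix with known entries
  ids <- c("q1", "q2", "c1", "c2")
  S <- matrix(1, 4, 4, dimnames = list(ids, ids))
  S["q1", "c1"] <- S["c1", "q1"] <- 0.5
  S["q2", "c2"] <- S["c2", "q2"] <- 0.8
  S["q1", "c2"] <- S["c2", "q1"] <- 0.1
  S["q2", "c1"] <- S["c1", "q2"] <- 0.9
  lib <- microLib()  # unused when simMatrix is supplied
  r <- pairSimilarity(lib, c("q1", "q2"), c("c1", "c2"), simMatrix = S)
  expect_equal(r$score, 0.4)  # max(0.5*0.8, 0.1*0.9)
  expect_equal(r$matching, "direct")
  ## identity: candidate equals query
  r2 <- pairSimilarity(lib, c("q1", "q2"), c("q1", "q2"), simMatrix = S)
  expect_equal(r2$score, 1)
  ## annihilation: a zero factor in both matchings
  S["q1", "c1"] <- S["c1", "q1"] <- 0
  S["q1", "c2"] <- S["c2", "q1"] <- 0
  r3 <- pairSimilarity(lib, c("q1", "q2"), c("c1", "c2"), simMatrix = S)
  expect_equal(r3$score, 0)
})

test_that("exemplar selection matches the exhaustive oracle on toy worlds", {
  for (seed in c(3, 17, 31)) {
    w <- generateWorld(nDrugs = 10, baseRate = 0.2, lambda = 4, seed = seed)
    cfg <- runConfig(kExemplars = 3, seed = seed)
    S <- similarityMatrix(w@library, "tanimoto", cfg)
    posPairs <- interactionPairs(w@interactions)
    negU <- ddicl:::.negativeUniverse(w@library, w@interactions)
    for (i in seq_len(min(4, nrow(posPairs)))) {
      q <- sort(posPairs[i, ])
      got <- selectPositiveExemplars(q, w@interactions, 3, cfg, S)
      want <- exhaustiveTopK(q, posPairs, S, 3, "exclude_pair")
      expect_identical(paste(got$id1, got$id2, sep = "|"), want)
      gotN <- mineHardNegatives(q, w@library, w@interactions, 3, cfg, S)
      wantN <- exhaustiveTopK(q, negU, S, 3, "exclude_pair")
      expect_identical(paste(gotN$id1, gotN$id2, sep = "|"), wantN)
    }
  }
})

test_that("k = 0 yields empty selections and k beyond availability warns", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[1, ])
  expect_equal(nrow(selectPositiveExemplars(q, w@interactions, 0, cfg, S)),
               0)
  expect_warning(
    got <- selectPositiveExemplars(q, w@interactions, 10000, cfg, S),
    "available")
  expect_equal(nrow(got), nInteractions(w@interactions) - 1)
})

test_that("leakage policies keep the query out of the exemplars", {
  w <- tinyWorld()
  S <- similarityMatrix(w@library, "tanimoto", tinyConfig())
  q <- sort(interactionPairs(w@interactions)[1, ])
  cfgPair <- runConfig(kExemplars = 4, leakagePolicy = "exclude_pair")
  es <- buildExemplarSet(q, w@library, w@interactions, 4, cfgPair, S)
  tab <- exemplarTable(es)
  expect_false(any(tab$id1 == q[1] & tab$id2 == q[2]))
  cfgDrug <- runConfig(kExemplars = 4, leakagePolicy = "exclude_drugs")
  es2 <- buildExemplarSet(q, w@library, w@interactions, 4, cfgDrug, S)
  tab2 <- exemplarTable(es2)
  expect_false(any(tab2$id1 %in% q | tab2$id2 %in% q))
})

test_that("score ties break on the lexicographic canonical pair key", {
  ids <- c("a", "b", "c", "d", "e")
  S <- matrix(0.5, 5, 5, dimnames = list(ids, ids)); diag(S) <- 1
  lib <- DrugLibrary(ids, smiles = rep("CCO", 5), canonicalize = FALSE)
  is <- InteractionSet(rbind(c("c", "e"), c("b", "e"), c("b", "c")), lib)
  cfg <- runConfig(kExemplars = 1)
  ## all candidate scores tie at 0.25: the smallest canonical key wins
  got <- selectPositiveExemplars(c("a", "d"), is, 1, cfg, S)
  expect_equal(paste(got$id1, got$id2, sep = "|"), "b|c")
})

test_that("hard-negative mining subsamples deterministically under a cap", {
  w <- tinyWorld()
  cfg <- runConfig(kExemplars = 3, candidateCap = 20, seed = 5)
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[2, ])
  n1 <- mineHardNegatives(q, w@library, w@interactions, 3, cfg, S)
  n2 <- mineHardNegatives(q, w@library, w@interactions, 3, cfg, S)
  expect_identical(n1, n2)
  ## a different seed may rank a different subsample
  cfg2 <- runConfig(kExemplars = 3, candidateCap = 20, seed = 6)
  n3 <- mineHardNegatives(q, w@library, w@interactions, 3, cfg2, S)
  expect_true(is.data.frame(n3))
})

test_that("exemplar sets are sorted, labelled and deterministic", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[1, ])
  e1 <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
  e2 <- buildExemplarSet(q, w@library, w@interactions, 2, cfg, S)
  expect_identical(e1@positives, e2@positives)
  expect_identical(e1@negatives, e2@negatives)
  expect_false(is.unsorted(rev(e1@positives$score)))
  expect_false(is.unsorted(rev(e1@negatives$score)))
  tab <- exemplarTable(e1)
  expect_setequal(unique(tab$label), c("positive", "negative"))
  expect_false(is.unsorted(rev(tab$score)))
})

test_that("the fast CV retrieval path equals the public selectors", {
  w <- generateWorld(nDrugs = 12, baseRate = 0.2, lambda = 4, seed = 3)
  cfg <- runConfig(kExemplars = 3, seed = 2)
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  ids <- drugIds(w@library)
  posPairs <- interactionPairs(w@interactions)
  negU <- ddicl:::.negativeUniverse(w@library, w@interactions)
  pc <- ddicl:::.pairCandidates(ids, posPairs)
  nc <- ddicl:::.pairCandidates(ids, negU)
  for (pol in c("exclude_pair", "exclude_drugs")) {
    cfgp <- runConfig(kExemplars = 3, leakagePolicy = pol)
    for (i in seq_len(min(5, nrow(posPairs)))) {
      q <- sort(posPairs[i, ])
      qa <- match(q[1], ids); qb <- match(q[2], ids)
      expect_equal(ddicl:::.topCandidates(pc, S, qa, qb, 3, pol),
                   selectPositiveExemplars(q, w@interactions, 3, cfgp, S))
      expect_equal(ddicl:::.topCandidates(nc, S, qa, qb, 3, pol),
                   mineHardNegatives(q, w@library, w@interactions, 3, cfgp,
                                     S, universe = negU))
    }
  }
})

test_that("random exemplar sets are seeded and score-sorted", {
  w <- tinyWorld()
  cfg <- tinyConfig()
  S <- similarityMatrix(w@library, "tanimoto", cfg)
  q <- sort(interactionPairs(w@interactions)[1, ])
  r1 <- randomExemplarSet(q, w@library, w@interactions, 2, cfg, S, seed = 9)
  r2 <- randomExemplarSet(q, w@library, w@interactions, 2, cfg, S, seed = 9)
  expect_identical(r1@positives, r2@positives)
  expect_identical(r1@negatives, r2@negatives)
  expect_false(is.unsorted(rev(exemplarTable(r1)$score)))
})
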