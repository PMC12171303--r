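## Shared fixtures, built in code and memoized for the session.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

## A hand-written 6-drug library with simple, distinct molecules.
microLib <- function() memoFixture("microLib", {
  DrugLibrary(
    id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    name = c("ethanol", "benzene", "acetic acid", "ethylamine",
             "phenol", "toluene"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O", "CCN", "Oc1ccccc1",
               "Cc1ccccc1"))
})

## Interactions over microLib: 4 known positives.
microInteractions <- function() memoFixture("microInteractions", {
  InteractionSet(rbind(c("d1", "d2"), c("d1", "d3"), c("d2", "d5"),
                       c("d4", "d6")), microLib())
})

## A small synthetic world shared by pipeline-level tests.
tinyWorld <- function() memoFixture("tinyWorld",
  generateWorld(nDrugs = 16, baseRate = 0.15, lambda = 4, seed = 42))

tinyConfig <- function() runConfig(kExemplars = 2, seed = 7)

## Seeded random fingerprint as a 0/1 vector.
randomBits <- function(n, p = 0.3) as.integer(stats::runif(n) < p)

## Seeded random labelled molecular-style graph with <= maxNodes nodes.
randomGraph <- function(maxNodes = 6, labels = c("C", "N", "O")) {
  n <- sample.int(maxNodes, 1)
  nodes <- sample(labels, n, replace = TRUE)
  edges <- NULL
  if (n >= 2) {
    all <- t(utils::combn(n, 2))
    pick <- stats::runif(nrow(all)) < 0.45
    edges <- all[pick, , drop = FALSE]
  }
  if (is.null(edges) || nrow(edges) == 0) edges <- matrix(integer(), 0, 2)
  molGraph(nodes, edges)
}
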