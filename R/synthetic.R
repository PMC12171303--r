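## Synthetic offline test worlds: a fragment-assembled molecule library and
## a planted interaction structure in which structurally similar drugs tend
## to share interaction partners.

## Chainable SMILES fragments: every fragment is valid both mid-chain and
## terminally, so seeded concatenations parse (assembly is still validated
## and re-drawn on the rare invalid combination). Rings re-use ring-bond
## label 1, which is legal once the previous ring is closed.
.FRAGMENTS <- c("C", "CC", "CCC", "O", "N", "S", "C(=O)", "C(=O)N",
                "C(C)", "C(Cl)", "C(F)", "C(O)", "C(N)", "C=C",
                "c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccsc1", "c1ccoc1",
                "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "c1ccc2ccccc2c1",
                "C(=O)O", "C#N", "OC(=O)", "N(C)", "C(=S)", "c1cnccn1",
                "C1CCSCC1")

## Small terminal decorations for within-series analogues.
.DECORATIONS <- c("C", "CC", "O", "N", "C(F)", "C(Cl)")

#' Generate a synthetic drug library
#'
#' Molecules are assembled by seeded concatenation of curated, chainable
#' SMILES fragments (alkyl chains, rings, common functional groups), which
#' guarantees parseable structures without a generative model. The library
#' emulates the congeneric series of real screening collections: a set of
#' prototype scaffolds (6-9 fragments each), with every drug either the
#' parent compound of its series or a terminally decorated analogue (0-2
#' small substituents). Within-series pairs are therefore structurally very
#' similar while cross-series pairs are not — the structure retrieval needs
#' to find.
#'
#' @param nDrugs number of drugs (`>= 4`).
#' @param seed generation seed.
#' @param nPrototypes number of prototype scaffolds (default `nDrugs / 8`,
#'   at least 4): the expected congeneric-series size is
#'   `nDrugs / nPrototypes`.
#' @return A [DrugLibrary-class] with names/ids `drug_0001`, ...
#' @examples
#' lib <- generateLibrary(12, seed = 7)
#' nDrugs(lib)
#' @export
generateLibrary <- function(nDrugs, seed = 1,
                            nPrototypes = max(4, round(nDrugs / 8))) {
  stopifnot(nDrugs >= 4)
  smiles <- withSeed(seed, {
    protos <- lapply(seq_len(nPrototypes), function(i)
      sample(.FRAGMENTS, sample(6:9, 1), replace = TRUE))
    vapply(seq_len(nDrugs), function(i) {
      series <- ((i - 1) %% nPrototypes) + 1
      for (attempt in 1:50) {
        fr <- protos[[series]]
        nDec <- sample(0:2, 1, prob = c(0.4, 0.45, 0.15))
        if (nDec > 0)
          fr <- c(fr, sample(.DECORATIONS, nDec, replace = TRUE))
        s <- paste(fr, collapse = "")
        if (!is.na(canonicalizeSmiles(s))) return(s)
        ## invalid assembly: re-draw the prototype for this series
        protos[[series]] <<- sample(.FRAGMENTS, sample(6:9, 1),
                                    replace = TRUE)
      }
      stop("could not assemble a valid molecule after 50 attempts")
    }, character(1))
  })
  ids <- sprintf("drug_%04d", seq_len(nDrugs))
  DrugLibrary(ids, ids, smiles, canonicalize = TRUE)
}

#' Plant an interaction structure over a drug library
#'
#' Latent-factor link model with a structural coupling: each drug gets a
#' latent vector `z_i ~ N(0, I_d)` and each unordered pair an edge with
#' probability `plogis(alpha + z_i . z_j + lambda * tanimoto(i, j))`, where
#' the Tanimoto similarity is computed on the same hashed circular
#' fingerprints the retriever uses (a deliberate idealization: the planted
#' signal is detectable by construction). The intercept `alpha` is
#' calibrated by bisection so the expected edge density matches `baseRate`.
#'
#' @param library a [DrugLibrary-class].
#' @param d latent dimension (default 1).
#' @param baseRate target edge density in `(0, 0.5)`.
#' @param lambda similarity-coupling strength (`>= 0`); 0 removes any
#'   association between structure and interactions.
#' @param seed generation seed.
#' @param config fingerprint parameters for the coupling term.
#' @return list with `interactions` ([InteractionSet-class]), `latent`
#'   (n x d matrix) and `alpha`.
#' @export
plantInteractions <- function(library, d = 1, baseRate = 0.05, lambda = 4,
                              seed = 1, config = runConfig()) {
  stopifnot(baseRate > 0, baseRate < 0.5, lambda >= 0, d >= 1)
  n <- nDrugs(library)
  ids <- drugIds(library)
  Tm <- similarityMatrix(library, "tanimoto", config)
  up <- which(upper.tri(Tm), arr.ind = TRUE)
  res <- withSeed(childSeed(seed, "latent"), {
    z <- matrix(stats::rnorm(n * d), n, d)
    eta0 <- (tcrossprod(z))[up] + lambda * Tm[up]
    ## bisection on the intercept for expected density = baseRate
    lo <- -50; hi <- 50
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      dens <- mean(stats::plogis(mid + eta0))
      if (abs(dens - baseRate) < 1e-10) break
      if (dens > baseRate) hi <- mid else lo <- mid
    }
    if (abs(mean(stats::plogis(mid + eta0)) - baseRate) > baseRate / 10)
      stop("density calibration failed")
    list(z = z, alpha = mid, eta0 = eta0)
  })
  edge <- withSeed(childSeed(seed, "edges"), {
    stats::runif(nrow(up)) < stats::plogis(res$alpha + res$eta0)
  })
  pairs <- cbind(ids[up[edge, 1]], ids[up[edge, 2]])
  rownames(res$z) <- ids
  list(interactions = InteractionSet(pairs, library), latent = res$z,
       alpha = res$alpha)
}

#' Generate a complete synthetic world
#'
#' Library plus planted interactions; fully reproducible from the
#' parameters and seed.
#'
#' @inheritParams plantInteractions
#' @inheritParams generateLibrary
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- generateWorld(nDrugs = 20, baseRate = 0.1, lambda = 4, seed = 3)
#' w
#' @export
generateWorld <- function(nDrugs = 200, d = 1, baseRate = 0.05, lambda = 4,
                          seed = 1, config = runConfig()) {
  lib <- generateLibrary(nDrugs, seed = childSeed(seed, "library"))
  pl <- plantInteractions(lib, d = d, baseRate = baseRate, lambda = lambda,
                          seed = childSeed(seed, "interactions"),
                          config = config)
  new("SyntheticWorld", library = lib, interactions = pl$interactions,
      latent = pl$latent,
      params = list(n_drugs = nDrugs, d = d, base_rate = baseRate,
                    lambda = lambda, seed = as.integer(seed),
                    alpha = pl$alpha))
}

#' Write a synthetic world to disk
#'
#' Emits `drugs.csv` and `interactions.tsv` in the package's table formats,
#' with the generation parameters embedded as `#`-comment headers, so a
#' world is reloadable with [loadDrugTable()] / [loadInteractionList()] and
#' self-describing.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- vapply(names(world@params), function(k)
    sprintf("# %s: %s", k, format(world@params[[k]], digits = 15)),
    character(1))
  drugPath <- file.path(dir, "drugs.csv")
  con <- file(drugPath, "wb"); writeLines(hdr, con)
  writeLines("id,name,smiles", con)
  d <- drugTable(world@library)
  writeLines(paste(d$id, d$name, d$smiles, sep = ","), con)
  close(con)
  intPath <- file.path(dir, "interactions.tsv")
  con <- file(intPath, "wb"); writeLines(hdr, con)
  p <- interactionPairs(world@interactions)
  if (nrow(p)) writeLines(paste(p[, 1], p[, 2], sep = "\t"), con)
  close(con)
  invisible(dir)
}
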