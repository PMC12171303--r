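## SMILES handling (via Open Babel through ChemmineR/ChemmineOB) and the
## hashed circular (Morgan-style) fingerprint.

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to Open Babel canonical form. Canonicalization is
#' idempotent: applying it to an already-canonical string is a no-op.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where the input does
#'   not parse.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    tok <- strsplit(trimws(out), "[ \t\n]+")[[1]]
    if (length(tok) == 0 || !nzchar(tok[1])) NA_character_ else tok[1]
  }, character(1), USE.NAMES = FALSE)
}

## Convert a vector of (valid) SMILES to MolGraph objects in one openbabel
## round trip. Implicit hydrogens are not materialized: graphs are heavy-atom
## graphs, matching fingerprint practice.
.molGraphs <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(as.character(smiles)))
  lapply(seq_along(smiles), function(i) {
    m <- sdf[[i]]
    ab <- ChemmineR::atomblock(m)
    bb <- ChemmineR::bondblock(m)
    nodes <- sub("_[0-9]+$", "", rownames(ab))
    edges <- if (is.null(dim(bb)) || nrow(bb) == 0) matrix(integer(), 0, 2)
             else cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    ## single-atom molecules carry a zero-filled placeholder bond row
    edges <- edges[edges[, 1] >= 1 & edges[, 2] >= 1, , drop = FALSE]
    molGraph(nodes, edges)
  })
}

#' Molecular graph of a SMILES string
#'
#' @param smiles a single valid SMILES string.
#' @return A [MolGraph-class] over the heavy atoms.
#' @examples
#' molGraphFromSmiles("CCO")
#' @export
molGraphFromSmiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  if (is.na(canonicalizeSmiles(smiles)))
    stop("invalid SMILES: ", smiles)
  .molGraphs(smiles)[[1]]
}

## Neighbour lists of a MolGraph.
.adjacency <- function(g) {
  n <- length(g@nodes)
  nbr <- vector("list", n)
  e <- g@edges
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1]; b <- e[i, 2]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  nbr
}

#' Hashed circular (Morgan-style) fingerprint
#'
#' Computes a binary fingerprint by hashing circular atom environments of
#' increasing radius, in the spirit of ECFP/Morgan fingerprints: each atom
#' starts from an invariant derived from its element symbol and heavy-atom
#' degree; at each round the invariant is re-hashed together with the sorted
#' invariants of the bonded neighbours; every environment hash from radius 0
#' up to `radius` sets one bit modulo `nbits`. The construction depends only
#' on the molecular graph, so any SMILES spelling of the same molecule yields
#' identical bits.
#'
#' @param x a SMILES string or a [MolGraph-class].
#' @param radius maximum environment radius (default 2).
#' @param nbits fingerprint length in bits (default 2048).
#' @return A [Fingerprint-class].
#' @examples
#' fp <- morganFingerprint("CCO")
#' length(fp@bits)
#' @export
morganFingerprint <- function(x, radius = 2, nbits = 2048) {
  g <- if (is(x, "MolGraph")) x else molGraphFromSmiles(x)
  if (length(g@nodes) == 0) stop("empty molecule")
  fingerprint(.morganBits(g, radius, nbits), nbits = nbits)
}

## Environment hashes -> on-bit positions for one graph.
.morganBits <- function(g, radius, nbits) {
  nbr <- .adjacency(g)
  deg <- lengths(nbr)
  inv <- vapply(seq_along(g@nodes), function(i)
    intVecHash(c(utf8ToInt(g@nodes[i]), deg[i])), numeric(1))
  env <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_along(inv), function(i) {
      ns <- nbr[[i]]
      intVecHash(c(r, inv[i], sort(inv[ns])))
    }, numeric(1))
    env <- c(env, inv)
  }
  sort(unique(as.integer(env %% nbits) + 1L))
}

#' Fingerprint matrix of a drug library
#'
#' One fingerprint per drug, as a dense 0/1 matrix (drugs x bits) suitable
#' for vectorized similarity computation.
#'
#' @param library a [DrugLibrary-class].
#' @param radius,nbits fingerprint parameters (defaults per [runConfig()]).
#' @return numeric matrix with rownames = drug ids.
#' @export
fingerprintMatrix <- function(library, radius = 2, nbits = 2048) {
  n <- nDrugs(library)
  M <- matrix(0, n, nbits, dimnames = list(drugIds(library), NULL))
  if (n == 0) return(M)
  graphs <- .molGraphs(drugSmiles(library))
  for (i in seq_len(n)) M[i, .morganBits(graphs[[i]], radius, nbits)] <- 1
  M
}
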