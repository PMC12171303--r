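## Independent brute-force oracles. These deliberately share no code with
## the implementation paths they check.

## WL subtree-pattern kernel by explicit enumeration: each node's depth-r
## subtree pattern is built recursively as a nested string, and the kernel
## counts all cross-graph node pairs with identical patterns, summed over
## depths 0..h.
bruteForceWL <- function(g1, g2, h) {
  nbrs <- function(g) {
    n <- length(g@nodes)
    out <- rep(list(integer()), n)
    e <- g@edges
    if (nrow(e)) for (i in seq_len(nrow(e))) {
      out[[e[i, 1]]] <- c(out[[e[i, 1]]], e[i, 2])
      out[[e[i, 2]]] <- c(out[[e[i, 2]]], e[i, 1])
    }
    out
  }
  pattern <- function(g, nb, v, depth) {
    if (depth == 0) return(g@nodes[v])
    sub <- sort(vapply(nb[[v]], function(u) pattern(g, nb, u, depth - 1),
                       character(1)))
    paste0(pattern(g, nb, v, depth - 1), "[", paste(sub, collapse = "|"),
           "]")
  }
  nb1 <- nbrs(g1); nb2 <- nbrs(g2)
  total <- 0
  for (r in 0:h) {
    p1 <- vapply(seq_along(g1@nodes), function(v) pattern(g1, nb1, v, r),
                 character(1))
    p2 <- vapply(seq_along(g2@nodes), function(v) pattern(g2, nb2, v, r),
                 character(1))
    for (a in p1) total <- total + sum(p2 == a)
  }
  total
}

## AUC by direct comparison of every positive-negative pair.
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Average precision by walking the ranking and accumulating precision at
## each positive.
bruteForceAp <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  hits <- 0; ap <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      hits <- hits + 1
      ap <- ap + hits / i
    }
  }
  ap / sum(labels == 1)
}

## Exhaustive exemplar selection: score every candidate pair, sort by
## (-score, canonical key), take k.
exhaustiveTopK <- function(query, candidates, S, k, policy) {
  if (nrow(candidates) == 0) return(character())
  keys <- paste(pmin(candidates[, 1], candidates[, 2]),
                pmax(candidates[, 1], candidates[, 2]), sep = "|")
  qkey <- paste(min(query), max(query), sep = "|")
  keep <- if (policy == "exclude_drugs")
    !(candidates[, 1] %in% query | candidates[, 2] %in% query)
  else keys != qkey
  candidates <- candidates[keep, , drop = FALSE]
  keys <- keys[keep]
  sc <- vapply(seq_len(nrow(candidates)), function(i) {
    max(S[query[1], candidates[i, 1]] * S[query[2], candidates[i, 2]],
        S[query[1], candidates[i, 2]] * S[query[2], candidates[i, 1]])
  }, numeric(1))
  keys[order(-sc, keys)][seq_len(min(k, length(keys)))]
}
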