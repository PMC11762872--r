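# Fitch parsimony over the 12-letter alphabet. State sets are bitmasks;
# gaps and wildcards are missing data (the full state set). The unrooted
# binary tree is evaluated rooted at its first tip, which makes every
# internal combine binary and the count exact.

fitch_sets <- function(msa, states) {
  m <- msa_matrix(msa)
  full <- bitwShiftL(1L, length(states)) - 1L
  idx <- match(m, states)
  sets <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  matrix(sets, nrow = nrow(m), dimnames = dimnames(m))
}

# adjacency-list postorder from an arbitrary root vertex
tree_adjacency <- function(tree) {
  ntip <- length(tree$tip.label)
  adj <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Fitch parsimony score of an alignment on a tree
#'
#' Per-site set-intersection count over the 12-state alphabet, summed over
#' sites (pattern-compressed). Gaps/wildcards contribute the full state
#' set and never force a change.
#' @param msa data.frame with columns `id`, `symbols`.
#' @param tree unrooted (or rooted) `ape::phylo`; tip labels must match
#'   alignment ids.
#' @return integer parsimony score.
#' @export
fitch_parsimony <- function(msa, tree) {
  if (!setequal(tree$tip.label, msa$id))
    stopf("fitch_parsimony: tree labels do not match alignment ids")
  states <- translation_table()$symbol
  sets <- fitch_sets(msa, states)
  # pattern compression
  key <- apply(sets[tree$tip.label, , drop = FALSE], 2, paste, collapse = ",")
  tab <- table(key)
  cols <- match(names(tab), key)
  w <- as.numeric(tab)
  S <- sets[tree$tip.label, cols, drop = FALSE]
  ntip <- length(tree$tip.label)
  adj <- tree_adjacency(tree)
  total <- 0
  # iterative DFS from tip 1
  root <- 1L
  parent <- rep(NA_integer_, length(adj))
  order <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (is.na(parent[u]) && u != root) {
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  nodeset <- vector("list", length(adj))
  for (v in rev(order)) {
    if (v <= ntip) {
      nodeset[[v]] <- S[tree$tip.label[v], ]
      next
    }
    kids <- setdiff(adj[[v]], if (is.na(parent[v])) integer(0) else parent[v])
    acc <- NULL
    for (u in kids) {
      cs <- nodeset[[u]]
      if (is.null(acc)) { acc <- cs; next }
      inter <- bitwAnd(acc, cs)
      empty <- inter == 0L
      total <- total + sum(w[empty])
      inter[empty] <- bitwOr(acc[empty], cs[empty])
      acc <- inter
    }
    nodeset[[v]] <- acc
  }
  # combine the root tip with its single child
  child <- setdiff(adj[[root]], NA)
  rootset <- S[tree$tip.label[root], ]
  childset <- nodeset[[child[1]]]
  empty <- bitwAnd(rootset, childset) == 0L
  total <- total + sum(w[empty])
  as.integer(round(total))
}

#' Maximum-parsimony tree search
#'
#' Exhaustive over all unrooted topologies for small taxon sets (<= 8 by
#' default; Fitch scoring is cheap), otherwise first-improvement NNI
#' hill-climbing from the NJ tree.
#' @param msa data.frame with columns `id`, `symbols`.
#' @param exhaustive_max exhaustive enumeration bound.
#' @return list with `tree` (no branch lengths from parsimony; unit
#'   lengths attached) and `score`.
#' @export
mp_search <- function(msa, exhaustive_max = 8) {
  n <- nrow(msa)
  if (n < 3) stopf("mp_search requires >= 3 taxa")
  if (n <= exhaustive_max) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = msa$id)
    best <- NULL; best_score <- Inf
    for (k in seq_along(trees)) {
      tr <- trees[[k]]  # [[ expands the compressed tip labels
      s <- fitch_parsimony(msa, tr)
      if (s < best_score) { best <- tr; best_score <- s }
    }
  } else {
    best <- neighbor_joining(dist_matrix(msa, "jc12"))
    best_score <- fitch_parsimony(msa, best)
    repeat {
      improved <- FALSE
      nbrs <- phangorn::nni(best)
      for (k in seq_along(nbrs)) {
        nb <- nbrs[[k]]
        s <- fitch_parsimony(msa, nb)
        if (s < best_score) {
          best <- nb; best_score <- s; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  best$edge.length <- rep(1, nrow(best$edge))
  list(tree = best, score = best_score)
}
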