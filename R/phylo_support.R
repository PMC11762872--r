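# Bootstrap, bipartition support mapping, outgroup rooting and
# Robinson-Foulds distance.

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaf set in two; the split is keyed by
#' the sorted labels of the side not containing the alphabetically first
#' label, so keys are comparable across trees with the same leaf set.
#' @param tree an `ape::phylo` (rooted or unrooted).
#' @return character vector of split keys.
#' @export
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  all_labels <- sort(tree$tip.label)
  ref <- all_labels[1]
  below <- node_descendant_tips(tree)
  keys <- character(0)
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    tips <- below[[v]]
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next
    side <- if (ref %in% tips) setdiff(all_labels, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# labels of tips below each node (node indices as in tree$edge)
node_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Bootstrap replicate trees from an encoded alignment
#'
#' Resamples alignment columns with replacement (sequence and structure
#' jointly, since the encoding fuses them) and rebuilds a tree per
#' replicate.
#' @param msa data.frame with columns `id`, `symbols`.
#' @param method tree builder: `"nj"`, `"mp"` or `"ml"`.
#' @param B number of pseudo-replicates (paper default: 100).
#' @param seed RNG seed for the column resampling.
#' @param model substitution model used by the `"ml"` builder.
#' @param correction distance correction for the `"nj"` builder
#'   (`"jc12"` or `"p"`; the latter avoids saturation errors on extreme
#'   replicates).
#' @return list of `B` `phylo` trees.
#' @export
bootstrap_trees <- function(msa, method = c("nj", "mp", "ml"), B = 100,
                            seed = 42, model = model_jc12(),
                            correction = "jc12") {
  method <- match.arg(method)
  if (B < 1) stopf("bootstrap_trees: B must be >= 1")
  m <- msa_matrix(msa)
  nc <- ncol(m)
  build <- switch(method,
    nj = function(x) neighbor_joining(dist_matrix(x, correction)),
    mp = function(x) mp_search(x)$tree,
    # replicates use NNI from the NJ start (exhaustive enumeration per
    # replicate would make a 100-replicate ML bootstrap intractable)
    ml = function(x) ml_search(x, model, exhaustive_max = 0)$tree)
  with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rep_msa <- data.frame(id = msa$id,
                            symbols = apply(m[, cols, drop = FALSE], 1, collapse),
                            stringsAsFactors = FALSE)
      build(rep_msa)
    })
  })
}

#' Map bootstrap support onto a reference tree
#'
#' The support of an internal edge is the percentage of replicate trees
#' containing the same bipartition, stored as an integer node label. All
#' values are stored; hiding values <= 50 is a display choice made at
#' write time ([write_newick()]).
#' @param reference `phylo` tree to annotate (rooted or unrooted).
#' @param replicates list of replicate trees with the same leaf set.
#' @return the reference tree with integer `node.label` support values
#'   (the root label is empty).
#' @export
map_support <- function(reference, replicates) {
  ntip <- length(reference$tip.label)
  all_labels <- sort(reference$tip.label)
  ref_lab <- all_labels[1]
  rep_keys <- lapply(replicates, tree_splits)
  below <- node_descendant_tips(reference)
  root <- ntip + 1L
  labels <- character(reference$Nnode)
  for (v in (ntip + 1):(ntip + reference$Nnode)) {
    tips <- below[[v]]
    if (v == root || length(tips) <= 1 || length(tips) >= ntip - 1) {
      labels[v - ntip] <- ""
      next
    }
    side <- if (ref_lab %in% tips) setdiff(all_labels, tips) else tips
    key <- paste(sort(side), collapse = "|")
    hits <- vapply(rep_keys, function(k) key %in% k, logical(1))
    labels[v - ntip] <- as.character(as.integer(round(100 * mean(hits))))
  }
  reference$node.label <- labels
  reference
}

#' Root a tree on the edge separating an outgroup
#'
#' The outgroup must induce a single edge in the unrooted tree
#' (monophyletic); the root is placed at the midpoint of that edge.
#' @param tree unrooted `ape::phylo`.
#' @param outgroup_labels character vector of outgroup tip labels.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  tips <- tree$tip.label
  missing <- setdiff(outgroup_labels, tips)
  if (length(missing) > 0)
    stopf("root_with_outgroup: outgroup label(s) not in tree: %s",
          paste(missing, collapse = ", "))
  if (length(setdiff(tips, outgroup_labels)) == 0)
    stopf("root_with_outgroup: outgroup cannot be the whole tree")
  if (length(outgroup_labels) > 1) {
    og <- sort(outgroup_labels)
    keys <- tree_splits(tree)
    all_labels <- sort(tips)
    side <- if (all_labels[1] %in% og) setdiff(all_labels, og) else og
    key <- paste(sort(side), collapse = "|")
    if (!(length(og) == length(tips) - 1 || key %in% keys))
      stopf(paste0("root_with_outgroup: outgroup {%s} is not monophyletic: ",
                   "no edge induces the bipartition {%s} | {%s}"),
            paste(og, collapse = ", "), paste(og, collapse = ", "),
            paste(setdiff(all_labels, og), collapse = ", "))
  }
  rooted <- ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the root edge evenly between its two children
  root <- length(rooted$tip.label) + 1L
  kid_edges <- which(rooted$edge[, 1] == root)
  if (length(kid_edges) == 2 && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[kid_edges])
    rooted$edge.length[kid_edges] <- tot / 2
  }
  rooted
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric bipartition distance (unnormalized count).
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stopf("rf_distance: trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
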