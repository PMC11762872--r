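#!/usr/bin/env Rscript
# Stage 5: NJ, MP and ML trees from the encoded alignment, 100
# column-bootstrap pseudo-replicates per method, outgroup rooting (t1)
# and support mapping; comparison of every tree against the generator's
# true tree.

suppressMessages(library(ssphylo))
seed <- 42
out <- "results"
aln <- read_encoded_fasta(file.path(out, "alignment.encoded.fasta"))
true_tree <- read_newick("results/data/true_tree.nwk")
true_tree$tip.label <- paste0(true_tree$tip.label, "_cistron")

dir.create(file.path(out, "trees"), showWarnings = FALSE)
outgroup <- "t1_cistron"
for (method in c("nj", "mp", "ml")) {
  tree <- switch(method,
    nj = neighbor_joining(dist_matrix(aln, "jc12")),
    mp = mp_search(aln)$tree,
    ml = ml_search(aln, model_jc12())$tree)
  tree <- root_with_outgroup(tree, outgroup)
  reps <- bootstrap_trees(aln, method = method, B = 100,
                          seed = seed + match(method, c("nj", "mp", "ml")))
  tree <- map_support(tree, reps)
  write_newick(tree, file.path(out, "trees", paste0(method, ".nwk")))
  # display convention: values above 50 shown at internal nodes
  write_newick(tree, file.path(out, "trees", paste0(method, "_display.nwk")),
               hide_support_at_or_below = 50)
  truth <- ape::keep.tip(true_tree, tree$tip.label)
  cat(sprintf("%s: RF to true tree = %d; support = [%s]\n", method,
              rf_distance(tree, truth),
              paste(setdiff(tree$node.label, ""), collapse = ", ")))
}
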