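# Distances, NJ, Fitch parsimony, 12-state ML, bootstrap, rooting, RF.

test_that("p-distance uses only comparable columns", {
  msa <- msa_df(c("a", "b"), c("BCGWAVBCGW", "BCGWAVBCGA"))
  expect_equal(p_distance(msa, 1, 2), 0.1)
  expect_equal(p_distance(msa, "a", "a"), 0)
  msa2 <- msa_df(c("a", "b"), c("BC-WX", "BCG-X"))  # 2 comparable, 0 diffs
  expect_equal(p_distance(msa2, 1, 2), 0)
  msa3 <- msa_df(c("a", "b"), c("----", "BCGW"))
  expect_error(p_distance(msa3, 1, 2), "no comparable")
})

test_that("jc12 correction matches its closed form and saturates", {
  expect_equal(jc12_distance(0), 0)
  expect_equal(jc12_distance(0.1), 0.1058868, tolerance = 1e-6)
  expect_error(jc12_distance(0.95), "saturation")
  expect_error(jc12_distance(11 / 12), "saturation")
  # inverse check: p implied by d = 0.3 under the model round-trips
  d <- 0.3
  p <- 11 / 12 * (1 - exp(-12 / 11 * d))
  expect_equal(jc12_distance(p), d)
})

test_that("NJ reconstructs additive matrices exactly (topology and lengths)", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  want <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(rf_distance(tr, want), 0L)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
  for (z in 1:100) {
    ad <- random_additive(sample(4:10, 1), seed = z)
    tr <- neighbor_joining(ad$D)
    expect_equal(rf_distance(tr, ad$tree), 0L, info = z)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)],
                 ad$D, tolerance = 1e-8)
  }
})

test_that("NJ handles 3 taxa, rejects asymmetry, and ties are deterministic", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")], D)
  bad <- D; bad[1, 2] <- 5
  expect_error(neighbor_joining(bad), "not symmetric")
  # equidistant matrix: same result on repeated calls
  E <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(E) <- 0
  expect_equal(ape::write.tree(neighbor_joining(E)),
               ape::write.tree(neighbor_joining(E)))
})

test_that("Fitch counts are exact on hand-checkable site patterns", {
  tab <- translation_table()
  # all identical -> 0
  msa <- msa_df(c("a", "b", "c"), rep("BBB", 3))
  tr <- ape::read.tree(text = "(a,b,c);")
  expect_equal(fitch_parsimony(msa, tr), 0L)
  # one variable site x,x,y -> 1
  msa2 <- msa_df(c("a", "b", "c"), c("B", "B", "C"))
  expect_equal(fitch_parsimony(msa2, tr), 1L)
  # xxyy on matching vs conflicting quartet: 1 vs 2
  msa3 <- msa_df(c("a", "b", "c", "d"), c("B", "B", "C", "C"))
  expect_equal(fitch_parsimony(msa3, ape::read.tree(text = "((a,b),(c,d));")), 1L)
  expect_equal(fitch_parsimony(msa3, ape::read.tree(text = "((a,c),(b,d));")), 2L)
  expect_error(fitch_parsimony(msa3, tr), "labels")
})

test_that("Fitch equals brute force over internal assignments", {
  tab <- translation_table()
  set.seed(41)
  for (z in 1:12) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- paste0("t", 1:n)
    nsites <- sample(2:4, 1)
    syms <- replicate(n, random_symbols(nsites, c(tab$symbol[1:4], "-")))
    msa <- msa_df(tr$tip.label, syms)
    got <- fitch_parsimony(msa, tr)
    m <- do.call(rbind, lapply(syms, function(s) strsplit(s, "")[[1]]))
    want <- 0
    for (s in seq_len(nsites)) {
      leaf <- match(m[, s], tab$symbol)
      names(leaf) <- tr$tip.label
      want <- want + brute_force_site_parsimony(tr, leaf)
    }
    expect_equal(got, as.integer(want), info = z)
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  tab <- translation_table()
  set.seed(43)
  n <- 6
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:n)
  syms <- replicate(n, random_symbols(30, tab$symbol))
  msa <- msa_df(tr$tip.label, syms)
  m <- do.call(rbind, lapply(syms, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- msa$id
  pd <- phangorn::phyDat(m, type = "USER", levels = tab$symbol)
  expect_equal(fitch_parsimony(msa, tr),
               as.integer(phangorn::parsimony(tr, pd)))
})

test_that("mp_search finds the parsimony-optimal quartet", {
  msa <- msa_df(c("a", "b", "c", "d"),
                c("BBBBCC", "BBBBCG", "CCCCCC", "CCCCCG"))
  res <- mp_search(msa)
  expect_equal(rf_distance(res$tree,
                           ape::read.tree(text = "((a,b),(c,d));")), 0L)
  expect_equal(res$score, fitch_parsimony(msa, res$tree))
})

test_that("two-taxon JC12 site likelihood matches the closed form", {
  # same symbol at both tips, total path length t:
  # (1/12) * (1/12 + (11/12) exp(-12 t / 11))
  msa <- msa_df(c("a", "b"), c("B", "B"))
  for (t in c(0.05, 0.3, 1)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    want <- log((1 / 12) * (1 / 12 + (11 / 12) * exp(-12 * t / 11)))
    expect_equal(log_likelihood(msa, tr, model_jc12()), want,
                 tolerance = 1e-10)
  }
  # saturation limit: any pattern tends to (1/12)^2
  tr <- ape::read.tree(text = "(a:40,b:40);")
  msa2 <- msa_df(c("a", "b"), c("B", "C"))
  expect_equal(log_likelihood(msa2, tr, model_jc12()), log(1 / 144),
               tolerance = 1e-4)
})

test_that("pruning equals direct summation over internal states", {
  tab <- translation_table()
  set.seed(47)
  for (z in 1:6) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
    nsites <- 2
    syms <- replicate(n, random_symbols(nsites, tab$symbol))
    msa <- msa_df(tr$tip.label, syms)
    got <- log_likelihood(msa, tr, model_jc12())
    m <- do.call(rbind, lapply(syms, function(s) strsplit(s, "")[[1]]))
    want <- 0
    for (s in seq_len(nsites)) {
      leaf <- match(m[, s], tab$symbol)
      names(leaf) <- tr$tip.label
      want <- want + log(brute_force_site_likelihood(tr, leaf, model_jc12()))
    }
    expect_equal(got, unname(want), tolerance = 1e-8, info = z)
  }
})

test_that("likelihood is invariant under rerooting (reversibility)", {
  tab <- translation_table()
  set.seed(53)
  n <- 5
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- paste0("t", 1:n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  msa <- msa_df(tr$tip.label, replicate(n, random_symbols(40, tab$symbol)))
  base <- log_likelihood(msa, tr, model_jc12())
  for (og in c("t2", "t4")) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(msa, rerooted, model_jc12()), base,
                 tolerance = 1e-8)
  }
})

test_that("zero-length branches at duplicate sequences keep a finite
           likelihood", {
  msa <- msa_df(c("a", "b", "c"), c("BCGW", "BCGW", "AAAA"))
  tr <- ape::read.tree(text = "(a:0,b:0,c:0.4);")
  expect_true(is.finite(log_likelihood(msa, tr, model_jc12())))
})

test_that("ml_search recovers an easy quartet and improves the likelihood", {
  tree <- simulate_tree(4, seed = 59)
  tree$edge.length <- rep(0.15, nrow(tree$edge))
  sim <- evolve_pairs(tree, sim_config(n_taxa = 4, site_count = 300, seed = 59))
  msa <- sim$true_alignment
  fit <- ml_search(msa, model_jc12())
  expect_equal(rf_distance(fit$tree, tree), 0L)
  # against an independent ML implementation on the same data and tree
  tab <- translation_table()
  m <- do.call(rbind, lapply(msa$symbols, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- msa$id
  pd <- phangorn::phyDat(m, type = "USER", levels = tab$symbol)
  pfit <- phangorn::pml(ape::unroot(fit$tree), pd)
  pfit <- phangorn::optim.pml(pfit, optEdge = TRUE,
                              control = phangorn::pml.control(trace = 0))
  expect_equal(fit$loglik, pfit$logLik, tolerance = 1e-3)
})

test_that("gtr12 builds a valid generator and nests jc12", {
  m <- model_gtr12(rates = rep(1, 66))
  expect_equal(max(abs(m$Q - model_jc12()$Q)), 0, tolerance = 1e-12)
  set.seed(61)
  m2 <- model_gtr12(rates = runif(66, 0.2, 3), pi = rep(1 / 12, 12))
  expect_equal(unname(rowSums(m2$Q)), rep(0, 12), tolerance = 1e-12)
  P <- prob_matrix(m2, 0.37)
  expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(P >= 0))
  # detailed balance for the reversible generator
  expect_equal(m2$pi * m2$Q, t(m2$pi * t(m2$Q)), tolerance = 1e-12)
})

test_that("bootstrap replicates are seeded, counted, and mapped as support", {
  tree <- simulate_tree(5, seed = 67)
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  sim <- evolve_pairs(tree, sim_config(n_taxa = 5, site_count = 200, seed = 67))
  msa <- sim$true_alignment
  reps1 <- bootstrap_trees(msa, "nj", B = 10, seed = 5)
  reps2 <- bootstrap_trees(msa, "nj", B = 10, seed = 5)
  expect_length(reps1, 10L)
  expect_equal(lapply(reps1, ape::write.tree), lapply(reps2, ape::write.tree))
  expect_error(bootstrap_trees(msa, "nj", B = 0), "B must be >= 1")
  # B = 1: supports are 0 or 100
  ref <- neighbor_joining(dist_matrix(msa, "jc12"))
  one <- map_support(ref, bootstrap_trees(msa, "nj", B = 1, seed = 9))
  vals <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(vals[!is.na(vals)] %in% c(0L, 100L)))
})

test_that("an alignment where every column supports one split maps 100", {
  msa <- msa_df(c("a", "b", "c", "d"),
                c(strrep("B", 30), strrep("B", 30),
                  strrep("C", 30), strrep("C", 30)))
  ref <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  reps <- bootstrap_trees(msa, "nj", B = 20, seed = 3, correction = "p")
  ann <- map_support(ref, reps)
  expect_true("100" %in% ann$node.label)
})

test_that("outgroup rooting splits the separating edge at its midpoint", {
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  utr <- ape::unroot(tr)
  rooted <- root_with_outgroup(utr, "a")
  expect_true(ape::is.rooted(rooted))
  og_edge <- which(rooted$edge[, 2] == which(rooted$tip.label == "a"))
  # two-leaf monophyletic outgroup
  rooted2 <- root_with_outgroup(utr, c("a", "b"))
  expect_true(ape::is.rooted(rooted2))
  kid_edges <- which(rooted2$edge[, 1] == length(rooted2$tip.label) + 1L)
  expect_equal(rooted2$edge.length[kid_edges[1]],
               rooted2$edge.length[kid_edges[2]])
  # outgroup split across the tree
  expect_error(root_with_outgroup(utr, c("a", "c")), "not monophyletic")
  expect_error(root_with_outgroup(utr, c("a", "b", "c", "d")), "whole tree")
  expect_error(root_with_outgroup(utr, "zz"), "not in tree")
})

test_that("RF distance counts conflicting bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(rf_distance(star, t1), 1L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
})
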