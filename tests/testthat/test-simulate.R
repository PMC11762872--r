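# Synthetic-data generator: trees, compensatory evolution, cistrons,
# template sets, and their ground truth.

test_that("simulated Yule trees have the right shape and reproduce", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)  # rooted: 1 internal edge
  tr50 <- simulate_tree(50, seed = 1)
  expect_equal(nrow(tr50$edge), 2 * 50 - 2)
  expect_identical(ape::write.tree(simulate_tree(8, seed = 9)),
                   ape::write.tree(simulate_tree(8, seed = 9)))
  expect_error(simulate_tree(2), "n >= 3")
})

test_that("the root structure realizes the helix specification", {
  cfg <- sim_config(site_count = 120)
  s <- ssphylo:::build_root_structure(cfg)
  expect_equal(nchar(s), 120L)
  core <- analyze_core(s)
  expect_equal(core$n_helices, 4L)
  expect_equal(core$helix_lengths, c(6L, 8L, 14L, 5L))
  expect_equal(core$longest_index, 3L)
  expect_error(sim_config(site_count = 50), "footprint")
  expect_error(sim_config(helix_spec = c(1, 8, 14, 5)), ">= 2")
})

test_that("zero branch lengths leave all leaves identical to the root", {
  tr <- simulate_tree(4, seed = 3)
  tr$edge.length[] <- 0
  sim <- evolve_pairs(tr, sim_config(n_taxa = 4, seed = 3))
  expect_true(all(sim$pairs$seq == sim$root$seq))
  expect_true(all(sim$pairs$structure == sim$root$structure))
})

test_that("every leaf keeps the four-helix core with the third longest", {
  tr <- simulate_tree(8, seed = 5)
  sim <- evolve_pairs(tr, sim_config(seed = 5))
  for (i in seq_len(nrow(sim$pairs))) {
    core <- analyze_core(sim$pairs$structure[i])
    expect_equal(core$n_helices, 4L)
    expect_equal(core$longest_index, 3L)
  }
  # pairs remain allowed pairs under compensatory evolution
  for (i in seq_len(nrow(sim$pairs))) {
    pr <- ssphylo:::db_pairs(sim$pairs$structure[i])
    cs <- strsplit(sim$pairs$seq[i], "")[[1]]
    expect_true(all(paste0(cs[pr[, 1]], cs[pr[, 2]]) %in%
                    ssphylo:::ALLOWED_PAIRS))
  }
})

test_that("substitution counts on a long edge match the model expectation", {
  # two-taxon tree with one long edge; unpaired sites evolve under the
  # state-preserving conditional of JC12, whose expected difference
  # fraction is computable in closed form from P(t)
  t_len <- 0.4
  tr <- ape::read.tree(text = sprintf("(t1:0,t2:%f);", t_len))
  cfg <- sim_config(n_taxa = 2, site_count = 2000, seed = 11)
  sim <- evolve_pairs(tr, cfg)
  s1 <- strsplit(sim$pairs$seq[match("t1", sim$pairs$id)], "")[[1]]
  s2 <- strsplit(sim$pairs$seq[match("t2", sim$pairs$id)], "")[[1]]
  unp <- which(strsplit(sim$root$structure, "")[[1]] == ".")
  obs <- mean(s1[unp] != s2[unp])
  P <- prob_matrix(model_jc12(), t_len)
  cond <- P[1:4, 1:4] / rowSums(P[1:4, 1:4])
  p_exp <- 1 - mean(diag(cond))
  sigma <- sqrt(p_exp * (1 - p_exp) / length(unp))
  expect_lt(abs(obs - p_exp), 3 * sigma + 1e-9)
})

test_that("the true alignment degaps to the leaf sequences (with indels)", {
  tr <- simulate_tree(6, seed = 13)
  cfg <- sim_config(n_taxa = 6, site_count = 120, indel_rate = 0.05, seed = 13)
  sim <- evolve_pairs(tr, cfg)
  tab <- translation_table()
  expect_equal(length(unique(nchar(sim$true_alignment$symbols))), 1L)
  for (i in seq_len(6)) {
    row <- sim$true_alignment$symbols[match(sim$pairs$id[i],
                                            sim$true_alignment$id)]
    expect_equal(gsub("-", "", row, fixed = TRUE),
                 encode_pair(sim$pairs$seq[i], sim$pairs$structure[i], tab))
  }
})

test_that("cistrons plant recoverable boundaries and fixed seeds reproduce", {
  pair <- list(id = "p1", seq = strrep("ACGU", 30))
  cis <- make_cistron(pair, sim_config(seed = 17))
  expect_equal(cis$truth$its2_start, 60L)
  expect_equal(cis$truth$its2_end, 180L)
  expect_true(cis$truth$full_flanks)
  expect_identical(make_cistron(pair, sim_config(seed = 17))$record$seq,
                   cis$record$seq)
  # end to end: annotation recovers the planted interval exactly
  hm <- default_flank_hmms()
  ann <- viterbi_annotate(cis$record$seq, hm$hmm5, hm$hmm3)
  expect_equal(ann$its2_start, cis$truth$its2_start)
  expect_equal(ann$its2_end, cis$truth$its2_end)
  expect_true(ann$full_proximal_stem)
  # truncated flank -> no full proximal stem downstream
  cis2 <- make_cistron(pair, sim_config(flank5_len = 10, seed = 17))
  ann2 <- viterbi_annotate(cis2$record$seq, hm$hmm5, hm$hmm3)
  expect_false(ann2$full_proximal_stem)
})

test_that("template sets span divergence levels with reproducible output", {
  tr <- simulate_tree(4, seed = 19)
  sim <- evolve_pairs(tr, sim_config(n_taxa = 4, seed = 19))
  tpl <- make_template_set(sim$pairs, k = 3,
                           divergence_levels = c(0, 0.3, 1.5), seed = 19)
  expect_equal(nrow(tpl), 3L)
  expect_identical(make_template_set(sim$pairs, k = 3,
                                     divergence_levels = c(0, 0.3, 1.5),
                                     seed = 19), tpl)
  # divergence 0: identical template -> full transfer downstream
  r <- transfer_structure(sim$pairs$seq[1], tpl[1, ])
  expect_equal(r$transfer_percent, 100)
  # a scrambled-sequence template drops to chance-level transfer, which
  # sits below the 50% homology filter (random target pairs are allowed
  # with probability ~6/16, so "unrelated" does not mean literally zero)
  set.seed(20)
  scram <- tpl[1, ]
  scram$seq <- paste(sample(strsplit(scram$seq, "")[[1]]), collapse = "")
  r2 <- transfer_structure(sim$pairs$seq[1], scram)
  expect_lt(r2$transfer_percent, 50)
  expect_error(make_template_set(sim$pairs, k = 0), "k must be >= 1")
})

test_that("generator output satisfies consumer invariants over fuzzed configs", {
  set.seed(23)
  for (z in 1:25) {
    n <- sample(3:6, 1)
    tr <- simulate_tree(n, seed = 100 + z)
    hs <- sample(3:12, 4)
    footprint <- 2 * sum(hs) + 4 * 4 + 3 * 5
    cfg <- sim_config(n_taxa = n,
                      site_count = footprint + sample(0:40, 1),
                      helix_spec = hs,
                      indel_rate = sample(c(0, 0.03), 1),
                      seed = 200 + z)
    sim <- evolve_pairs(tr, cfg)
    for (i in seq_len(n))
      expect_silent(ssphylo:::validate_pair(sim$pairs$seq[i],
                                            sim$pairs$structure[i],
                                            sim$pairs$id[i]))
    enc <- encode_pairs(sim$pairs)  # would error on any invalid pair
    expect_equal(nchar(enc$symbols), nchar(sim$pairs$seq))
  }
})
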