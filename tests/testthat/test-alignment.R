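# 12x12 sequence-structure alignment: pairwise Gotoh DP, guide tree,
# progressive multiple alignment.

test_that("the default scoring model separates the two channels", {
  m <- scoring_model12()
  expect_true(isSymmetric(m$S))
  expect_equal(unname(m$S["A", "A"]), 4)   # same nucleotide, same state
  expect_equal(unname(m$S["A", "B"]), 0)   # same nucleotide, other state
  expect_equal(unname(m$S["A", "C"]), 1)   # other nucleotide, same state
  expect_equal(unname(m$S["A", "D"]), -3)  # both differ
  expect_equal(unname(m$S["X", "A"]), 0)   # wildcard is neutral
  # diagonal dominates every row of the 12-letter block
  core <- m$S[1:12, 1:12]
  expect_true(all(diag(core) >= apply(core - diag(99, 12), 1, max)))
})

test_that("identical strings align without gaps at the diagonal score", {
  m <- scoring_model12()
  al <- pairwise_align("BCGWAV", "BCGWAV", m)
  expect_equal(al$a, "BCGWAV")
  expect_equal(al$b, "BCGWAV")
  expect_equal(al$score, 6 * 4)
})

test_that("aligning against a single-symbol substring yields gap columns", {
  m <- scoring_model12()
  al <- pairwise_align("BCGW", "C", m)
  expect_equal(nchar(al$a), 4L)
  expect_equal(sum(strsplit(al$b, "")[[1]] == "-"), 3L)
  expect_error(pairwise_align("", "A", m), "non-empty")
  expect_error(pairwise_align("Z", "A", m), "not in scoring alphabet")
})

test_that("pairwise DP equals the brute-force alignment oracle", {
  tab <- translation_table()
  set.seed(17)
  for (z in 1:100) {
    m <- scoring_model12(match_nuc = sample(1:3, 1),
                         mismatch_nuc = -sample(0:2, 1),
                         match_state = sample(1:3, 1),
                         mismatch_state = -sample(1:3, 1),
                         gap_open = -sample(2:8, 1),
                         gap_extend = -sample(1:2, 1))
    a <- random_symbols(sample(1:6, 1), tab$symbol)
    b <- random_symbols(sample(1:6, 1), tab$symbol)
    got <- pairwise_align(a, b, m)$score
    want <- brute_force_align_score(a, b, m$S, m$gap_open, m$gap_extend)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("alignment score is invariant under alphabet relabeling", {
  tab <- translation_table()
  perm <- c(LETTERS[14:25])  # NOPQRSTUVWXY -> fresh 12 letters
  tab2 <- tab
  tab2$symbol <- perm
  class(tab2) <- class(tab)
  m1 <- scoring_model12(tab)
  m2 <- scoring_model12(tab2)
  set.seed(23)
  for (z in 1:20) {
    a <- random_symbols(sample(3:10, 1), tab$symbol)
    b <- random_symbols(sample(3:10, 1), tab$symbol)
    map <- stats::setNames(tab2$symbol, tab$symbol)
    a2 <- paste(map[strsplit(a, "")[[1]]], collapse = "")
    b2 <- paste(map[strsplit(b, "")[[1]]], collapse = "")
    expect_equal(pairwise_align(a, b, m1)$score,
                 pairwise_align(a2, b2, m2)$score)
  }
})

test_that("guide trees put clearly similar pairs as neighbors", {
  tab <- translation_table()
  set.seed(29)
  base1 <- random_symbols(40, tab$symbol)
  base2 <- random_symbols(40, tab$symbol)
  mutate <- function(s, k) {
    cs <- strsplit(s, "")[[1]]
    idx <- sample(length(cs), k)
    cs[idx] <- sample(tab$symbol, k, replace = TRUE)
    paste(cs, collapse = "")
  }
  enc <- msa_df(c("a1", "a2", "b1", "b2"),
                c(base1, mutate(base1, 3), base2, mutate(base2, 3)))
  D <- encoded_identity_dist(enc)
  # four-point condition favors a1a2 | b1b2
  expect_lt(D["a1", "a2"] + D["b1", "b2"],
            min(D["a1", "b1"] + D["a2", "b2"],
                D["a1", "b2"] + D["a2", "b1"]))
  tr <- guide_tree(enc)
  expect_equal(rf_distance(tr, ape::read.tree(text = "((a1,a2),(b1,b2));")), 0L)
  # two sequences: a single edge
  tr2 <- guide_tree(enc[1:2, ])
  expect_equal(ape::Ntip(tr2), 2L)
})

test_that("three identical sequences give a zero-length star guide tree", {
  enc <- msa_df(c("a", "b", "c"), rep("BCGWAV", 3))
  tr <- guide_tree(enc)
  expect_equal(sum(tr$edge.length), 0)
})

test_that("progressive alignment of identical sequences is gapless and the
           two-sequence case matches pairwise alignment", {
  tab <- translation_table()
  enc <- msa_df(c("a", "b", "c"), rep("BCGWAVBCGW", 3))
  al <- progressive_align(enc)
  expect_equal(al$symbols, rep("BCGWAVBCGW", 3))
  set.seed(31)
  enc2 <- msa_df(c("x", "y"), c(random_symbols(12, tab$symbol),
                                random_symbols(9, tab$symbol)))
  al2 <- progressive_align(enc2)
  pw <- pairwise_align(enc2$symbols[1], enc2$symbols[2])
  expect_equal(al2$symbols, c(pw$a, pw$b))
})

test_that("degapping alignment rows reproduces the inputs", {
  tab <- translation_table()
  set.seed(37)
  enc <- msa_df(paste0("s", 1:5),
                vapply(1:5, function(z) random_symbols(sample(20:30, 1),
                                                       tab$symbol),
                       character(1)))
  al <- progressive_align(enc)
  expect_equal(nchar(al$symbols), rep(nchar(al$symbols[1]), 5))
  expect_equal(gsub("-", "", al$symbols, fixed = TRUE), enc$symbols)
  expect_equal(al$id, enc$id)
})

test_that("low-divergence generator alignments are recovered almost fully", {
  tree <- simulate_tree(6, seed = 101)
  tree$edge.length <- tree$edge.length * 0.05 / mean(tree$edge.length)
  cfg <- sim_config(site_count = 120, indel_rate = 0.02, seed = 101)
  sim <- evolve_pairs(tree, cfg)
  enc <- encode_pairs(sim$pairs)
  est <- progressive_align(enc)
  rec <- score_alignment_recovery(sim$true_alignment, est)
  expect_gte(rec, 0.95)
})
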