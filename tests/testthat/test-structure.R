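# Structure prediction: homology transfer, constrained folding, helix core.

test_that("transfer onto an identical sequence reproduces the template", {
  tpl <- list(id = "tpl", seq = "GGGAAACCC", structure = "(((...)))")
  r <- transfer_structure("GGGAAACCC", tpl)
  expect_equal(r$transfer_percent, 100)
  expect_equal(r$structure, tpl$structure)
})

test_that("deleting one partner loses one of three pairs (about 66.7%)", {
  # hand-derivable: all optimal alignments gap one terminal C, so exactly
  # one template pair maps to a gap and 2/3 transfer
  tpl <- list(id = "tpl", seq = "GGGAAACCC", structure = "(((...)))")
  r <- transfer_structure("GGGAAACC", tpl)
  expect_equal(r$transfer_percent, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(r$n_transferred, 2L)
})

test_that("a target that cannot pair transfers nothing", {
  tpl <- list(id = "tpl", seq = "GGGAAACCC", structure = "(((...)))")
  r <- transfer_structure("AAAAAAAAA", tpl)
  expect_equal(r$transfer_percent, 0)
  expect_equal(r$structure, ".........")
})

test_that("templates without pairs are rejected", {
  tpl <- list(id = "flat", seq = "ACGU", structure = "....")
  expect_error(transfer_structure("ACGU", tpl), "no base pairs")
})

test_that("best-template selection maximizes transfer with list-order ties", {
  templates <- data.frame(
    id = c("self", "unrelated"),
    seq = c("GGGAAACCC", "UUUUUUUUU"),
    structure = c("(((...)))", "(.......)"),
    stringsAsFactors = FALSE)
  best <- select_best_template("GGGAAACCC", templates)
  expect_equal(best$template_name, "self")
  expect_equal(best$transfer_percent, 100)
  # ties: two identical templates -> the first wins
  tied <- templates[c(1, 1), ]
  tied$id <- c("first", "second")
  expect_equal(select_best_template("GGGAAACCC", tied)$template_name, "first")
  expect_error(select_best_template("ACGU", templates[0, ]), "empty template")
})

test_that("homology filter boundary is inclusive at the threshold", {
  results <- lapply(c(40, 50, 100 * 2 / 3), function(p)
    list(id = paste0("r", p), transfer_percent = p))
  fh <- filter_by_homology(results, 50)
  expect_length(fh$kept, 2L)
  expect_length(fh$discarded, 1L)
  expect_equal(fh$discarded[[1]]$transfer_percent, 40)
  expect_length(filter_by_homology(list(), 50)$kept, 0L)
  expect_length(filter_by_homology(results, 0)$discarded, 0L)
})

test_that("constrained_fold recovers the hairpin and obeys constraints", {
  expect_equal(constrained_fold("GGGAAACCC"), "(((...)))")
  expect_equal(constrained_fold("AAAA"), "....")
  expect_equal(constrained_fold("GGGAAACCC", forbidden = 0:8), ".........")
  expect_error(constrained_fold("ACGU", min_loop = -1), "min_loop")
})

test_that("constrained_fold matches exhaustive enumeration on short sequences", {
  set.seed(13)
  weights <- c(GC = 3, AU = 2, GU = 1)
  score_structure <- function(seq, struct) {
    pr <- ssphylo:::db_pairs(struct)
    if (nrow(pr) == 0) return(0)
    cs <- strsplit(seq, "")[[1]]
    sum(vapply(seq_len(nrow(pr)), function(r) {
      p <- paste0(cs[pr[r, 1]], cs[pr[r, 2]])
      if (p %in% c("GC", "CG")) weights[["GC"]]
      else if (p %in% c("AU", "UA")) weights[["AU"]]
      else if (p %in% c("GU", "UG")) weights[["GU"]] else 0
    }, numeric(1)))
  }
  for (z in 1:200) {
    len <- sample(4:12, 1)
    seq <- paste(sample(NUCS4, len, replace = TRUE), collapse = "")
    nforb <- sample(0:2, 1)
    forb <- if (nforb > 0) sample(0:(len - 1), nforb) else integer(0)
    ml <- sample(0:3, 1)
    struct <- constrained_fold(seq, forbidden = forb, min_loop = ml)
    got <- score_structure(seq, struct)
    want <- brute_force_fold_score(seq, forbidden = forb, min_loop = ml)
    expect_equal(got, want, info = sprintf("%s forb=%s ml=%d", seq,
                                           paste(forb, collapse = ","), ml))
    # constraints respected
    if (length(forb) > 0)
      expect_true(all(strsplit(struct, "")[[1]][forb + 1] == "."))
  }
})

test_that("helix-core analysis counts exterior helices and the longest", {
  expect_equal(analyze_core("((...))((...))")$n_helices, 2L)
  # four exterior stems of 3, 4, 8, 2 pairs
  s <- paste0("(((...)))", ".", "((((...))))", ".",
              "((((((((...))))))))", ".", "((...))")
  core <- analyze_core(s)
  expect_equal(core$n_helices, 4L)
  expect_equal(core$helix_lengths, c(3L, 4L, 8L, 2L))
  expect_equal(core$longest_index, 3L)
  empty <- analyze_core(".........")
  expect_equal(empty$n_helices, 0L)
  expect_true(is.na(empty$longest_index))
})

test_that("subhelix pairs count toward their exterior helix", {
  # one exterior helix with an internal loop and a nested subhelix
  s <- "((..((...))..))"
  core <- analyze_core(s)
  expect_equal(core$n_helices, 1L)
  expect_equal(core$helix_lengths, 4L)
})

test_that("exterior loop positions exclude everything under a pair", {
  s <- "..((...))..((.))."
  pos <- exterior_loop_positions(s)
  expect_equal(pos, c(0L, 1L, 9L, 10L, 16L))
})

test_that("transfer output is always a valid nested pair and the percent
           survives unalignable flanks", {
  set.seed(99)
  for (z in 1:25) {
    pr <- random_pair(sample(15:30, 1))
    if (!grepl("\\(", pr$structure)) next
    tpl <- list(id = "t", seq = pr$seq, structure = pr$structure)
    target <- random_pair(sample(15:30, 1))$seq
    r <- transfer_structure(target, tpl)
    expect_silent(ssphylo:::validate_pair(r$seq, r$structure, "modeled"))
    expect_gte(r$transfer_percent, 0)
    expect_lte(r$transfer_percent, 100)
  }
  # short unalignable flank on an identical target keeps full transfer
  tpl <- list(id = "t", seq = "GGGGGAAAACCCCC", structure = "(((((....)))))")
  base <- transfer_structure("GGGGGAAAACCCCC", tpl)$transfer_percent
  flanked <- transfer_structure("UGGGGGAAAACCCCCU", tpl)$transfer_percent
  expect_equal(base, 100)
  expect_equal(flanked, 100)
})
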