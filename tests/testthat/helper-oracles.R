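# Independent brute-force oracles. These deliberately avoid the package's
# dynamic programs: alignments are enumerated as explicit move paths,
# structures as explicit nested pair sets, HMM scores as explicit state
# paths, parsimony and likelihood as explicit sums over internal-node
# assignments.

NUCS4 <- c("A", "C", "G", "U")

# ---- alignment ----------------------------------------------------------

# all global alignments of lengths n x m as move strings over M/D/I
enumerate_alignments <- function(n, m) {
  out <- list()
  rec <- function(i, j, acc) {
    if (i == n && j == m) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(acc, "M"))
    if (i < n) rec(i + 1L, j, c(acc, "D"))
    if (j < m) rec(i, j + 1L, c(acc, "I"))
  }
  rec(0L, 0L, character(0))
  out
}

score_alignment_path <- function(moves, ca, cb, S, gap_open, gap_extend) {
  score <- 0
  pa <- pb <- 0L
  prev <- ""
  for (mv in moves) {
    if (mv == "M") {
      pa <- pa + 1L; pb <- pb + 1L
      score <- score + S[ca[pa], cb[pb]]
    } else {
      if (mv == "D") pa <- pa + 1L else pb <- pb + 1L
      score <- score + if (mv == prev) gap_extend else gap_open
    }
    prev <- mv
  }
  score
}

brute_force_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  paths <- enumerate_alignments(length(ca), length(cb))
  max(vapply(paths, score_alignment_path, numeric(1),
             ca = ca, cb = cb, S = S,
             gap_open = gap_open, gap_extend = gap_extend))
}

# ---- folding ------------------------------------------------------------

# all nested pair sets on 1..n respecting min_loop and a pairability test
enumerate_structures <- function(n, can_pair, min_loop) {
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    out <- list()
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s  # i unpaired
    ks <- seq_len(j)
    ks <- ks[ks >= i + min_loop + 1L]
    for (k in ks) {
      if (!can_pair(i, k)) next
      for (inner in rec(i + 1L, k - 1L))
        for (outer in rec(k + 1L, j))
          out[[length(out) + 1L]] <- c(list(c(i, k)), inner, outer)
    }
    out
  }
  rec(1L, n)
}

brute_force_fold_score <- function(seq, forbidden = integer(0), min_loop = 3,
                                   weights = c(GC = 3, AU = 2, GU = 1)) {
  cs <- strsplit(seq, "")[[1]]
  wt <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) weights[["GC"]]
    else if (p %in% c("AU", "UA")) weights[["AU"]]
    else if (p %in% c("GU", "UG")) weights[["GU"]]
    else 0
  }
  blocked <- rep(FALSE, length(cs))
  blocked[forbidden + 1L] <- TRUE
  can_pair <- function(i, j) !blocked[i] && !blocked[j] && wt(cs[i], cs[j]) > 0
  structs <- enumerate_structures(length(cs), can_pair, min_loop)
  best <- 0
  for (s in structs) {
    sc <- sum(vapply(s, function(p) wt(cs[p[1]], cs[p[2]]), numeric(1)))
    if (sc > best) best <- sc
  }
  best
}

# ---- profile HMM --------------------------------------------------------

# exhaustive glocal Viterbi: enumerate every state path with flank-free
# entry/exit, same scoring semantics as hmm_search()
brute_force_hmm_score <- function(hmm, seq) {
  x <- match(strsplit(seq, "")[[1]], NUCS4)
  n <- length(x)
  L <- hmm$L
  lem <- log(hmm$match_emis) - log(0.25)
  em <- function(k, i) if (is.na(x[i])) 0 else lem[k, x[i]]
  lmm <- log(hmm$mm); lmi <- log(hmm$mi); lmd <- log(hmm$md)
  lim <- log(hmm$im); lii <- log(hmm$ii)
  ldm <- log(hmm$dm); ldd <- log(hmm$dd)
  lb1 <- log1p(-hmm$md)
  best <- -Inf
  # state: "M"/"I"/"D", column k, consumed position i, accumulated score
  rec <- function(state, k, i, acc) {
    if (k == L && state %in% c("M", "D")) {
      if (acc > best) best <<- acc
      if (state == "D") return(invisible())
    }
    if (state == "M" || state == "I") {
      if (k < L && i < n) rec("M", k + 1L, i + 1L,
                              acc + (if (state == "M") lmm else lim) +
                                em(k + 1L, i + 1L))
      if (state == "M") {
        if (i < n) rec("I", k, i + 1L, acc + lmi)
        if (k < L) rec("D", k + 1L, i, acc + lmd)
      } else if (i < n) rec("I", k, i + 1L, acc + lii)
    } else {  # D
      if (k < L && i < n) rec("M", k + 1L, i + 1L, acc + ldm + em(k + 1L, i + 1L))
      if (k < L) rec("D", k + 1L, i, acc + ldd)
    }
  }
  for (i0 in 0:n) {
    if (i0 < n) rec("M", 1L, i0 + 1L, lb1 + em(1L, i0 + 1L))  # enter at M1
    rec("D", 1L, i0, lmd)                                      # enter at D1
  }
  unname(best)
}

# ---- parsimony ----------------------------------------------------------

# minimum substitutions for one site over explicit internal assignments;
# missing (NA) leaf states are also minimized over
brute_force_site_parsimony <- function(tree, leaf_states, nstates = 12) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  states <- leaf_states[tree$tip.label]
  free_leaves <- which(is.na(states))
  best <- Inf
  assign_internal <- function(int_assign, leaf_assign) {
    full <- c(leaf_assign, int_assign)
    cost <- sum(full[edges[, 1]] != full[edges[, 2]])
    if (cost < best) best <<- cost
  }
  rec_leaves <- function(idx, leaf_assign) {
    if (idx > length(free_leaves)) {
      grid <- rep(1L, nint)
      repeat {
        assign_internal(grid, leaf_assign)
        pos <- 1L
        while (pos <= nint) {
          grid[pos] <- grid[pos] + 1L
          if (grid[pos] <= nstates) break
          grid[pos] <- 1L
          pos <- pos + 1L
        }
        if (pos > nint) break
      }
      return(invisible())
    }
    for (s in seq_len(nstates)) {
      leaf_assign[free_leaves[idx]] <- s
      rec_leaves(idx + 1L, leaf_assign)
    }
  }
  rec_leaves(1L, states)
  best
}

# ---- likelihood ---------------------------------------------------------

# direct summation over all internal-node state assignments for one site
brute_force_site_likelihood <- function(tree, leaf_states, model) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  P <- lapply(seq_len(nrow(edges)), function(e)
    ssphylo::prob_matrix(model, tree$edge.length[e]))
  root <- setdiff(edges[, 1], edges[, 2])[1]
  states <- leaf_states[tree$tip.label]
  total <- 0
  grid <- rep(1L, nint)
  repeat {
    full <- c(states, grid)
    lik <- model$pi[full[root]]
    for (e in seq_len(nrow(edges)))
      lik <- lik * P[[e]][full[edges[e, 1]], full[edges[e, 2]]]
    total <- total + lik
    pos <- 1L
    while (pos <= nint) {
      grid[pos] <- grid[pos] + 1L
      if (grid[pos] <= 12L) break
      grid[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > nint) break
  }
  total
}

# ---- misc ---------------------------------------------------------------

# stack-based balanced-nested-word check for dot-bracket strings
balanced_oracle <- function(structure) {
  depth <- 0L
  for (c in strsplit(structure, "")[[1]]) {
    if (c == "(") depth <- depth + 1L
    if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  depth == 0L
}

# additive distance matrix from a random topology with known branch lengths
random_additive <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- round(stats::runif(nrow(tree$edge), 0.1, 2), 3)
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}

# random valid sequence-structure pair
random_pair <- function(len, p_pair = 0.35) {
  struct <- rep(".", len)
  i <- 1L
  while (i <= len - 5L) {
    if (stats::runif(1) < p_pair) {
      j <- i + 4L + sample.int(max(1L, len - i - 4L), 1L)
      if (j <= len && all(struct[i:j] == ".")) {
        struct[i] <- "("; struct[j] <- ")"
      }
    }
    i <- i + 1L
  }
  # fix crossings by regeneration through a stack pass
  s <- paste(struct, collapse = "")
  seq <- sample(NUCS4, len, replace = TRUE)
  pr <- tryCatch(ssphylo:::db_pairs(s), error = function(e) NULL)
  if (is.null(pr)) return(random_pair(len, p_pair))
  if (nrow(pr) > 0) {
    types <- c("GC", "CG", "AU", "UA", "GU", "UG")
    pick <- sample(types, nrow(pr), replace = TRUE)
    seq[pr[, 1]] <- substr(pick, 1, 1)
    seq[pr[, 2]] <- substr(pick, 2, 2)
  }
  list(seq = paste(seq, collapse = ""), structure = s)
}

msa_df <- function(ids, symbols) {
  data.frame(id = ids, symbols = symbols, stringsAsFactors = FALSE)
}

random_symbols <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
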