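# Sequence-structure alignment under a 12x12 scoring matrix with affine
# gaps: pairwise (Gotoh) and progressive multiple alignment along an NJ
# guide tree ("once a gap, always a gap").

#' Default 12x12 sequence-structure scoring model
#'
#' The score of two encoded symbols is the sum of a nucleotide term and a
#' pairing-state term, so the two information channels fused by the
#' encoding are scored separately:
#' `(+2 same nucleotide / -1 different) + (+2 same state / -2 different)`.
#' The wildcard symbol scores 0 against everything. Terminal gaps are
#' penalized like internal gaps.
#'
#' @param table translation table fixing the alphabet.
#' @param match_nuc,mismatch_nuc nucleotide channel scores.
#' @param match_state,mismatch_state pairing-state channel scores.
#' @param gap_open,gap_extend affine gap costs (both <= 0).
#' @return list with the 13x13 matrix `S` (12 letters + wildcard),
#'   `gap_open`, `gap_extend`; class `ss_scoring_model`.
#' @export
scoring_model12 <- function(table = translation_table(),
                            match_nuc = 2, mismatch_nuc = -1,
                            match_state = 2, mismatch_state = -2,
                            gap_open = -8, gap_extend = -2) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  syms <- c(table$symbol, SS_WILDCARD)
  nuc <- c(table$nuc, NA)
  st <- c(table$state, NA)
  n <- length(syms)
  S <- matrix(0, n, n, dimnames = list(syms, syms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.na(nuc[i]) || is.na(nuc[j])) next  # wildcard scores 0
    S[i, j] <- (if (nuc[i] == nuc[j]) match_nuc else mismatch_nuc) +
      (if (st[i] == st[j]) match_state else mismatch_state)
  }
  model <- list(S = S, gap_open = gap_open, gap_extend = gap_extend,
                alphabet = table$symbol)
  class(model) <- "ss_scoring_model"
  model
}

#' Load a scoring matrix from TSV
#'
#' The TSV must be a square matrix with symbol row/column names; it is
#' symmetrized by averaging if needed.
#' @param path TSV file.
#' @param gap_open,gap_extend affine gap costs.
#' @return an `ss_scoring_model`.
#' @export
read_scoring_matrix <- function(path, gap_open = -8, gap_extend = -2) {
  S <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (nrow(S) != ncol(S) || !identical(rownames(S), colnames(S)))
    stopf("scoring matrix must be square with matching row/column names")
  S <- (S + t(S)) / 2
  model <- list(S = S, gap_open = gap_open, gap_extend = gap_extend,
                alphabet = setdiff(rownames(S), SS_WILDCARD))
  class(model) <- "ss_scoring_model"
  model
}

#' Global pairwise alignment of two encoded sequences
#'
#' Affine-gap global alignment maximizing the summed 12x12 scores (Gotoh
#' three-matrix DP). Tie-break is deterministic: match/mismatch is
#' preferred over deletion (gap in `b`) over insertion (gap in `a`).
#'
#' @param a,b encoded symbol strings (non-empty).
#' @param model an `ss_scoring_model`.
#' @return list with gapped strings `a`, `b` and the alignment `score`.
#' @export
pairwise_align <- function(a, b, model = scoring_model12()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stopf("pairwise_align requires non-empty sequences")
  res <- gotoh_align_chars(chars(a), chars(b), model$S,
                           model$gap_open, model$gap_extend)
  list(a = collapse(res$a), b = collapse(res$b), score = res$score)
}

aligned_identity <- function(ga, gb) {
  ca <- chars(ga); cb <- chars(gb)
  both <- ca != SS_GAP & cb != SS_GAP
  if (!any(both)) return(0)
  mean(ca[both] == cb[both])
}

#' Pairwise fractional-identity distances between encoded sequences
#'
#' d = 1 - identity, with identity the fraction of identical symbols over
#' columns where neither sequence is gapped in the pairwise alignment.
#' @param enc data.frame with columns `id`, `symbols`.
#' @param model scoring model used for the pairwise alignments.
#' @return symmetric distance matrix with ids as dimnames.
#' @export
encoded_identity_dist <- function(enc, model = scoring_model12()) {
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(enc$id, enc$id))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- pairwise_align(enc$symbols[i], enc$symbols[j], model)
    D[i, j] <- D[j, i] <- 1 - aligned_identity(al$a, al$b)
  }
  D
}

#' Guide tree for progressive alignment
#'
#' Neighbor-joining tree on pairwise-alignment fractional-identity
#' distances (d = 1 - identity).
#' @param enc data.frame with columns `id`, `symbols` (>= 2 rows).
#' @param model scoring model.
#' @return an `ape::phylo` tree.
#' @export
guide_tree <- function(enc, model = scoring_model12()) {
  n <- nrow(enc)
  if (n < 2) stopf("guide_tree requires >= 2 sequences")
  D <- encoded_identity_dist(enc, model)
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);", enc$id[1],
                                         fmt_num(D[1, 2] / 2), enc$id[2],
                                         fmt_num(D[1, 2] / 2))))
  }
  neighbor_joining(D)
}

profile_counts <- function(rows, alphabet) {
  # rows: character matrix (nseq x ncol); counts of non-gap symbols per column
  syms <- c(alphabet, SS_WILDCARD)
  t(vapply(seq_len(ncol(rows)), function(j)
    tabulate(match(rows[, j], syms), nbins = length(syms)),
    integer(length(syms))))  # ncol x nsym -> transposed below
}

merge_profiles <- function(A, B, model) {
  # A, B: list(ids, rows [matrix rows x cols])
  syms <- c(model$alphabet, SS_WILDCARD)
  CA <- profile_counts(A$rows, model$alphabet)  # La x nsym
  CB <- profile_counts(B$rows, model$alphabet)  # Lb x nsym
  Ssub <- model$S[syms, syms]
  nA <- rowSums(CA); nB <- rowSums(CB)
  smat <- (CA %*% Ssub %*% t(CB)) / outer(pmax(nA, 1), pmax(nB, 1))
  smat[nA == 0, ] <- 0
  smat[, nB == 0] <- 0
  res <- gotoh_core(smat, model$gap_open, model$gap_extend)
  La <- nrow(CA); Lb <- nrow(CB)
  ncols <- length(res$moves)
  out <- matrix(SS_GAP, nrow(A$rows) + nrow(B$rows), ncols)
  pa <- pb <- 0L
  for (k in seq_len(ncols)) {
    mv <- res$moves[k]
    if (mv != "I") { pa <- pa + 1L; out[seq_len(nrow(A$rows)), k] <- A$rows[, pa] }
    if (mv != "D") { pb <- pb + 1L; out[nrow(A$rows) + seq_len(nrow(B$rows)), k] <- B$rows[, pb] }
  }
  list(ids = c(A$ids, B$ids), rows = out)
}

#' Progressive multiple alignment of encoded sequences
#'
#' Profiles are merged in guide-tree postorder; profile-profile column
#' scores are the mean pairwise symbol score over non-gap symbols; gaps
#' once introduced are never removed. Row order of the result follows the
#' input.
#' @param enc data.frame with columns `id`, `symbols` (>= 2 rows).
#' @param model scoring model.
#' @param tree optional guide tree (defaults to [guide_tree()]).
#' @return data.frame with columns `id`, `symbols` (equal-length gapped
#'   strings).
#' @export
progressive_align <- function(enc, model = scoring_model12(), tree = NULL) {
  n <- nrow(enc)
  if (n < 2) stopf("progressive_align requires >= 2 sequences")
  if (n == 2) {
    al <- pairwise_align(enc$symbols[1], enc$symbols[2], model)
    return(data.frame(id = enc$id, symbols = c(al$a, al$b),
                      stringsAsFactors = FALSE))
  }
  if (is.null(tree)) tree <- guide_tree(enc, model)
  # deterministic rooting at the first input sequence
  rooted <- ape::root(tree, outgroup = enc$id[1], resolve.root = TRUE)
  rooted <- stats::reorder(rooted, "postorder")
  ntip <- length(rooted$tip.label)
  prof <- vector("list", ntip + rooted$Nnode)
  for (i in seq_len(ntip)) {
    sym <- enc$symbols[match(rooted$tip.label[i], enc$id)]
    prof[[i]] <- list(ids = rooted$tip.label[i],
                      rows = matrix(chars(sym), nrow = 1))
  }
  children <- split(rooted$edge[, 2], rooted$edge[, 1])
  # process internal nodes in postorder of edges (children always ready
  # by the time a parent's last child edge is reached)
  done <- logical(ntip + rooted$Nnode)
  for (k in seq_len(nrow(rooted$edge))) {
    parent <- rooted$edge[k, 1]
    if (done[parent]) next
    kids <- children[[as.character(parent)]]
    if (any(vapply(kids, function(x) is.null(prof[[x]]), logical(1)))) next
    acc <- prof[[kids[1]]]
    for (x in kids[-1]) acc <- merge_profiles(acc, prof[[x]], model)
    prof[[parent]] <- acc
    done[parent] <- TRUE
  }
  root <- rooted$edge[nrow(rooted$edge), 1]
  acc <- prof[[root]]
  sym <- apply(acc$rows, 1, collapse)
  data.frame(id = acc$ids, symbols = sym,
             stringsAsFactors = FALSE)[match(enc$id, acc$ids), ] -> out
  rownames(out) <- NULL
  out
}

#' Column-pair recovery of an estimated alignment
#'
#' Fraction of homologous residue pairs (two rows, both non-gap, same
#' column) in the reference alignment that are also aligned in the
#' estimate. 1 means every reference column was recovered.
#' @param reference,estimate data.frames with columns `id`, `symbols`;
#'   degapped rows must agree between the two.
#' @return numeric in [0, 1].
#' @export
score_alignment_recovery <- function(reference, estimate) {
  stopifnot(setequal(reference$id, estimate$id))
  res_index <- function(sym) {
    cs <- chars(sym)
    idx <- cumsum(cs != SS_GAP)
    idx[cs == SS_GAP] <- NA
    idx
  }
  key_pairs <- function(msa, i, j) {
    ri <- res_index(msa$symbols[i]); rj <- res_index(msa$symbols[j])
    ok <- !is.na(ri) & !is.na(rj)
    paste(ri[ok], rj[ok])
  }
  ids <- reference$id
  est <- estimate[match(ids, estimate$id), ]
  total <- 0L; hit <- 0L
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    ref_pairs <- key_pairs(reference, i, j)
    est_pairs <- key_pairs(est, i, j)
    total <- total + length(ref_pairs)
    hit <- hit + sum(ref_pairs %in% est_pairs)
  }
  if (total == 0L) return(1)
  hit / total
}
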