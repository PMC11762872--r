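# Distances on encoded alignments and neighbor-joining.

msa_matrix <- function(msa) {
  m <- do.call(rbind, lapply(msa$symbols, chars))
  rownames(m) <- msa$id
  m
}

#' Uncorrected p-distance between two alignment rows
#'
#' Proportion of differing symbols over columns where both rows carry a
#' non-gap, non-wildcard symbol; other columns are excluded entirely.
#' @param msa data.frame with columns `id`, `symbols` (equal lengths).
#' @param i,j row indices or ids.
#' @return numeric in [0, 1].
#' @export
p_distance <- function(msa, i, j) {
  if (is.character(i)) i <- match(i, msa$id)
  if (is.character(j)) j <- match(j, msa$id)
  a <- chars(msa$symbols[i]); b <- chars(msa$symbols[j])
  usable <- !(a %in% c(SS_GAP, SS_WILDCARD)) & !(b %in% c(SS_GAP, SS_WILDCARD))
  if (!any(usable))
    stopf("p_distance: no comparable columns between rows %s and %s",
          msa$id[i], msa$id[j])
  mean(a[usable] != b[usable])
}

#' Jukes-Cantor-type distance correction for a 12-state alphabet
#'
#' Closed form `d = -(11/12) * log(1 - (12/11) * p)` for the equal-rates
#' 12-state model; saturates (errors) at p >= 11/12.
#' @param p observed proportion of differing sites.
#' @return corrected distance (substitutions/site).
#' @examples
#' jc12_distance(0.1)  # ~0.10588
#' @export
jc12_distance <- function(p) {
  if (any(p < 0 | p >= 11 / 12))
    stopf("jc12_distance: saturation (p must lie in [0, 11/12))")
  -(11 / 12) * log(1 - (12 / 11) * p)
}

#' Pairwise distance matrix from an encoded alignment
#'
#' @param msa data.frame with columns `id`, `symbols`.
#' @param correction `"jc12"` (default) or `"p"` (uncorrected).
#' @return symmetric matrix with ids as dimnames.
#' @export
dist_matrix <- function(msa, correction = c("jc12", "p")) {
  correction <- match.arg(correction)
  m <- msa_matrix(msa)
  n <- nrow(m)
  usable <- !(m == SS_GAP | m == SS_WILDCARD)
  D <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    u <- usable[i, ] & usable[j, ]
    if (!any(u))
      stopf("dist_matrix: no comparable columns between %s and %s",
            msa$id[i], msa$id[j])
    p <- mean(m[i, u] != m[j, u])
    D[i, j] <- D[j, i] <- if (correction == "jc12") jc12_distance(p) else p
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister edge (their sum is preserved). Ties in the Q-criterion are
#' broken deterministically by the smallest (i, j) pair in the current
#' node order (original label order, join-created nodes appended).
#'
#' @param D symmetric distance matrix with zero diagonal; dimnames are the
#'   taxon labels.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stopf("neighbor_joining requires >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stopf("neighbor_joining: D is not symmetric")
  if (any(!is.finite(D))) stopf("neighbor_joining: non-finite distances")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels  # newick fragment per active node
  active <- seq_len(n)
  Dm <- D
  while (length(active) > 3) {
    r <- length(active)
    Ds <- Dm[active, active, drop = FALSE]
    R <- rowSums(Ds)
    Q <- (r - 2) * Ds - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    ai <- hits[1, 1]; aj <- hits[1, 2]
    i <- active[ai]; j <- active[aj]
    dij <- Ds[ai, aj]
    li <- dij / 2 + (R[ai] - R[aj]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_num(li),
                       frag[j], fmt_num(lj))
    # distances from the new node
    others <- setdiff(active, c(i, j))
    dnew <- (Dm[i, others] + Dm[j, others] - dij) / 2
    Dm <- rbind(cbind(Dm, 0), 0)
    u <- nrow(Dm)
    Dm[u, others] <- dnew
    Dm[others, u] <- dnew
    frag <- c(frag, newfrag)
    active <- c(others, u)
    active <- active[order(active)]
  }
  a <- active[1]; b <- active[2]; c <- active[3]
  la <- (Dm[a, b] + Dm[a, c] - Dm[b, c]) / 2
  lb <- (Dm[a, b] + Dm[b, c] - Dm[a, c]) / 2
  lc <- (Dm[a, c] + Dm[b, c] - Dm[a, b]) / 2
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  frag[a], fmt_num(max(la, 0)),
                  frag[b], fmt_num(max(lb, 0)),
                  frag[c], fmt_num(max(lc, 0)))
  ape::read.tree(text = text)
}
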