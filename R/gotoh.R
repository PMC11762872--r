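# Affine-gap global alignment engine (Gotoh three-matrix DP).
#
# Works on a precomputed column-score matrix so the same engine serves
# nucleotide alignment (structure transfer), 12-letter sequence-structure
# alignment, and profile-profile alignment. A gap run of length L costs
# gap_open + (L - 1) * gap_extend; switching gap direction re-opens.
# Traceback is deterministic: diagonal (match/mismatch) preferred over
# deletion (gap in b, consuming a) over insertion (gap in a, consuming b).

GOTOH_NEG <- -1e18
GOTOH_EPS <- 1e-9

gotoh_core <- function(smat, gap_open, gap_extend) {
  n <- nrow(smat)
  m <- ncol(smat)
  if (n == 0L && m == 0L) return(list(score = 0, moves = character(0)))
  if (n == 0L) return(list(score = gap_open + (m - 1) * gap_extend,
                           moves = rep("I", m)))
  if (m == 0L) return(list(score = gap_open + (n - 1) * gap_extend,
                           moves = rep("D", n)))
  M <- X <- Y <- matrix(GOTOH_NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- gap_open + (0:(n - 1)) * gap_extend
  Y[1, 2:(m + 1)] <- gap_open + (0:(m - 1)) * gap_extend
  js <- 2:(m + 1)
  for (i in 2:(n + 1)) {
    prevM <- M[i - 1, ]; prevX <- X[i - 1, ]; prevY <- Y[i - 1, ]
    Mi <- rep(GOTOH_NEG, m + 1L)
    Mi[js] <- smat[i - 1, ] + pmax(prevM[js - 1L], prevX[js - 1L], prevY[js - 1L])
    Xi <- pmax(prevM + gap_open, prevX + gap_extend, prevY + gap_open)
    # horizontal matrix via max-plus scan: Yi[j] = max_{k<j} base[k]+(j-1-k)*ge
    base <- pmax(Mi, Xi) + gap_open
    k <- seq_len(m + 1L)
    cz <- cummax(base - k * gap_extend)
    Yi <- rep(GOTOH_NEG, m + 1L)
    Yi[js] <- (js - 1L) * gap_extend + cz[js - 1L]
    M[i, ] <- Mi; X[i, ] <- Xi; Y[i, ] <- Yi
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  pick <- function(vals) which.max(vals + c(2, 1, 0) * GOTOH_EPS)
  state <- c("M", "X", "Y")[pick(c(M[i, j], X[i, j], Y[i, j]))]
  score <- max(M[i, j], X[i, j], Y[i, j])
  moves <- character(n + m)
  nm <- 0L
  while (i > 1L || j > 1L) {
    nm <- nm + 1L
    if (state == "M") {
      moves[nm] <- "M"
      i <- i - 1L; j <- j - 1L
      state <- c("M", "X", "Y")[pick(c(M[i, j], X[i, j], Y[i, j]))]
    } else if (state == "X") {
      moves[nm] <- "D"
      cur <- X[i, j]
      i <- i - 1L
      cand <- c(M[i, j] + gap_open, X[i, j] + gap_extend, Y[i, j] + gap_open)
      if (i == 1L && j == 1L) break
      state <- c("M", "X", "Y")[pick(ifelse(abs(cand - cur) < GOTOH_EPS,
                                            cand, GOTOH_NEG))]
    } else {
      moves[nm] <- "I"
      cur <- Y[i, j]
      j <- j - 1L
      cand <- c(M[i, j] + gap_open, X[i, j] + gap_open, Y[i, j] + gap_extend)
      if (i == 1L && j == 1L) break
      state <- c("M", "X", "Y")[pick(ifelse(abs(cand - cur) < GOTOH_EPS,
                                            cand, GOTOH_NEG))]
    }
  }
  list(score = score, moves = rev(moves[seq_len(nm)]))
}

# align two character vectors given a named score matrix
gotoh_align_chars <- function(ca, cb, S, gap_open, gap_extend) {
  ia <- match(ca, rownames(S))
  ib <- match(cb, colnames(S))
  if (anyNA(ia)) stopf("symbol '%s' not in scoring alphabet", ca[is.na(ia)][1])
  if (anyNA(ib)) stopf("symbol '%s' not in scoring alphabet", cb[is.na(ib)][1])
  smat <- S[ia, ib, drop = FALSE]
  res <- gotoh_core(matrix(smat, length(ia), length(ib)), gap_open, gap_extend)
  ga <- gb <- character(length(res$moves))
  pa <- pb <- 0L
  for (k in seq_along(res$moves)) {
    mv <- res$moves[k]
    if (mv != "I") { pa <- pa + 1L; ga[k] <- ca[pa] } else ga[k] <- SS_GAP
    if (mv != "D") { pb <- pb + 1L; gb[k] <- cb[pb] } else gb[k] <- SS_GAP
  }
  list(a = ga, b = gb, score = res$score, moves = res$moves)
}
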