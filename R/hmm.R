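# ITS2 annotation: small profile HMMs for the 5.8S end and the 28S start
# delimit the ITS2 inside a 5.8S-ITS2-28S fragment; the annotated region
# is then extended by the proximal-stem convention (25 nt into each
# flanking gene by default).
#
# The profile topology is the standard match/insert/delete layout with
# position-independent transition probabilities; search is "glocal": the
# model must be traversed from its first to its last column (entry/exit
# through delete states is allowed, at a cost), while the flanking
# sequence outside the hit is free. Scores are log-odds against a uniform
# background, so an empty hit scores 0.

#' Construct a profile HMM
#'
#' @param match_emis L x 4 matrix of match emission probabilities
#'   (columns A, C, G, U; rows sum to 1).
#' @param mm,mi,md match transitions (to next match / insert / delete).
#' @param im,ii insert transitions (to next match / self).
#' @param dm,dd delete transitions (to next match / next delete).
#' @param name model name.
#' @return object of class `profile_hmm`.
#' @export
profile_hmm <- function(match_emis, mm = 0.88, mi = 0.02, md = 0.10,
                        im = 0.6, ii = 0.4, dm = 0.3, dd = 0.7,
                        name = "profile") {
  match_emis <- as.matrix(match_emis)
  colnames(match_emis) <- NUCS
  if (any(abs(rowSums(match_emis) - 1) > 1e-9))
    stopf("profile_hmm: match emissions must sum to 1 per state")
  if (abs(mm + mi + md - 1) > 1e-9 || abs(im + ii - 1) > 1e-9 ||
      abs(dm + dd - 1) > 1e-9)
    stopf("profile_hmm: transition distributions must sum to 1")
  if (nrow(match_emis) < 1L) stopf("profile_hmm: need >= 1 match state")
  obj <- list(match_emis = match_emis, L = nrow(match_emis),
              mm = mm, mi = mi, md = md, im = im, ii = ii, dm = dm, dd = dd,
              name = name)
  class(obj) <- "profile_hmm"
  obj
}

#' Train a profile HMM from an ungapped motif alignment
#'
#' Maximum-likelihood match emissions with a pseudocount of 1 per
#' nucleotide; transition probabilities are the constructor defaults
#' (an ungapped alignment carries no indel information).
#' @param motifs character vector of equal-length ungapped sequences
#'   (or a data.frame with a `seq` column, e.g. from [read_fasta()]).
#' @param pseudocount added to each nucleotide count.
#' @param name model name.
#' @return a `profile_hmm`.
#' @export
build_profile_hmm <- function(motifs, pseudocount = 1, name = "motif") {
  if (is.data.frame(motifs)) motifs <- motifs$seq
  motifs <- vapply(motifs, normalize_seq, character(1), USE.NAMES = FALSE)
  L <- nchar(motifs[1])
  if (any(nchar(motifs) != L))
    stopf("build_profile_hmm: motif alignment must be ungapped (equal lengths)")
  mat <- do.call(rbind, lapply(motifs, chars))
  emis <- t(vapply(seq_len(L), function(k) {
    counts <- tabulate(match(mat[, k], NUCS), nbins = 4) + pseudocount
    counts / sum(counts)
  }, numeric(4)))
  profile_hmm(emis, name = name)
}

#' Glocal Viterbi search of a profile HMM against a sequence
#'
#' Finds the best-scoring placement of the full model (column 1 to column
#' L, delete entry/exit allowed) inside the sequence. Emission scores are
#' log-odds against a uniform background; insert states emit at
#' background. Returns the hit's half-open 0-based interval and log-odds.
#'
#' @param hmm a `profile_hmm`.
#' @param seq nucleotide string.
#' @return list with `start`, `end` (0-based half-open), `log_odds`.
#' @export
hmm_search <- function(hmm, seq) {
  seq <- normalize_seq(seq)
  x <- match(chars(seq), NUCS)          # N -> NA, scored at background
  n <- length(x)
  L <- hmm$L
  if (n == 0L) return(list(start = NA_integer_, end = NA_integer_,
                           log_odds = -Inf))
  NEG <- -1e18
  lem <- log(hmm$match_emis) - log(0.25) # L x 4 log-odds
  lmm <- log(hmm$mm); lmi <- log(hmm$mi); lmd <- log(hmm$md)
  lim <- log(hmm$im); lii <- log(hmm$ii)
  ldm <- log(hmm$dm); ldd <- log(hmm$dd)
  lb1 <- log1p(-hmm$md)                  # B -> M1
  # columns indexed i+1 for i = 0..n consumed characters
  VM <- VI <- VD <- matrix(NEG, L, n + 1L)
  SM <- SI <- SD <- matrix(NA_integer_, L, n + 1L)  # 0-based hit starts
  # i = 0: only delete chains from a begin at position 0
  VD[1L, 1L] <- lmd; SD[1L, 1L] <- 0L
  if (L > 1L) for (k in 2:L) {
    VD[k, 1L] <- VD[k - 1L, 1L] + ldd
    SD[k, 1L] <- 0L
  }
  for (i in seq_len(n)) {
    e <- if (is.na(x[i])) rep(0, L) else lem[, x[i]]
    ii1 <- i + 1L
    # match states: fresh begin (flank before position i is free) or
    # continuation from column k-1 at i-1
    VM[1L, ii1] <- e[1L] + lb1
    SM[1L, ii1] <- i - 1L
    if (L > 1L) {
      cm <- VM[1:(L - 1L), i] + lmm
      ci <- VI[1:(L - 1L), i] + lim
      cd <- VD[1:(L - 1L), i] + ldm
      best <- pmax(cm, ci, cd)
      VM[2:L, ii1] <- e[2:L] + best
      SM[2:L, ii1] <- ifelse(cm >= best, SM[1:(L - 1L), i],
                             ifelse(ci >= best, SI[1:(L - 1L), i],
                                    SD[1:(L - 1L), i]))
    }
    # insert states
    cm <- VM[, i] + lmi
    ci <- VI[, i] + lii
    VI[, ii1] <- pmax(cm, ci)
    SI[, ii1] <- ifelse(cm >= ci, SM[, i], SI[, i])
    # delete states: fresh begin at i, or chains off this column's matches
    VD[1L, ii1] <- lmd
    SD[1L, ii1] <- i
    if (L > 1L) for (k in 2:L) {
      cm <- VM[k - 1L, ii1] + lmd
      cd <- VD[k - 1L, ii1] + ldd
      if (cm >= cd) { VD[k, ii1] <- cm; SD[k, ii1] <- SM[k - 1L, ii1] }
      else { VD[k, ii1] <- cd; SD[k, ii1] <- SD[k - 1L, ii1] }
    }
  }
  # exit after column L from a match or delete state, trailing flank free
  endM <- VM[L, , drop = TRUE]
  endD <- VD[L, , drop = TRUE]
  tot <- pmax(endM, endD)
  i_best <- which.max(tot)
  s_best <- if (endM[i_best] >= endD[i_best]) SM[L, i_best] else SD[L, i_best]
  list(start = s_best, end = i_best - 1L, log_odds = tot[i_best])
}

#' Annotate the ITS2 inside a 5.8S-ITS2-28S fragment
#'
#' Locates the best occurrence of the 5.8S-end model and, downstream of
#' it, the 28S-start model (glocal Viterbi, log-odds). The ITS2 is the
#' region strictly between the two hits; the proximal interval extends it
#' by up to `L` nt into each flank, truncated at the sequence bounds.
#'
#' @param seq nucleotide string (a single cistron fragment).
#' @param hmm5 profile HMM for the 5.8S end (the last nucleotides of 5.8S).
#' @param hmm3 profile HMM for the 28S start.
#' @param L proximal-stem extension length (default 25 nt).
#' @param floor log-odds floor; a flank hit below it makes the annotation
#'   fail (the sequence is filtered later, not an error).
#' @param id record id carried into the result.
#' @return one-row data.frame with columns `id`, `ok`, `reason`,
#'   `its2_start`, `its2_end`, `proximal_start`, `proximal_end`,
#'   `full_proximal_stem`, `score` (all intervals 0-based half-open).
#' @export
viterbi_annotate <- function(seq, hmm5, hmm3, L = 25, floor = 0,
                             id = "<record>") {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  fail <- function(reason) data.frame(
    id = id, ok = FALSE, reason = reason, its2_start = NA_integer_,
    its2_end = NA_integer_, proximal_start = NA_integer_,
    proximal_end = NA_integer_, full_proximal_stem = FALSE,
    score = NA_real_, stringsAsFactors = FALSE)
  if (n < hmm5$L + hmm3$L) return(fail("annotation_failed"))
  h5 <- hmm_search(hmm5, seq)
  if (!is.finite(h5$log_odds) || h5$log_odds < floor)
    return(fail("annotation_failed"))
  rest_from <- h5$end  # 0-based offset of remaining sequence
  if (rest_from >= n) return(fail("annotation_failed"))
  h3 <- hmm_search(hmm3, substr(seq, rest_from + 1L, n))
  if (!is.finite(h3$log_odds) || h3$log_odds < floor)
    return(fail("annotation_failed"))
  its2_start <- h5$end
  its2_end <- rest_from + h3$start
  prox_start <- max(0L, its2_start - as.integer(L))
  prox_end <- min(n, its2_end + as.integer(L))
  data.frame(id = id, ok = TRUE, reason = NA_character_,
             its2_start = its2_start, its2_end = its2_end,
             proximal_start = prox_start, proximal_end = prox_end,
             full_proximal_stem = (its2_start - prox_start == L) &&
               (prox_end - its2_end == L),
             score = h5$log_odds + h3$log_odds, stringsAsFactors = FALSE)
}

#' Annotate a collection of cistron fragments
#' @param records data.frame from [read_fasta()].
#' @param hmm5,hmm3 flank profile HMMs.
#' @param L,floor see [viterbi_annotate()].
#' @return data.frame with one row per record.
#' @export
annotate_sequences <- function(records, hmm5, hmm3, L = 25, floor = 0) {
  out <- lapply(seq_len(nrow(records)), function(i)
    viterbi_annotate(records$seq[i], hmm5, hmm3, L = L, floor = floor,
                     id = records$id[i]))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep only records annotatable by the full proximal stem
#'
#' @param annotations data.frame from [annotate_sequences()].
#' @return list with `kept` and `discarded` (the latter with a `reason`
#'   column: `annotation_failed` or `truncated_proximal_stem`).
#' @export
filter_annotatable <- function(annotations) {
  reason <- ifelse(!annotations$ok, "annotation_failed",
                   ifelse(!annotations$full_proximal_stem,
                          "truncated_proximal_stem", NA_character_))
  keep <- is.na(reason)
  discarded <- annotations[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  list(kept = annotations[keep, , drop = FALSE], discarded = discarded)
}

#' Write annotations as TSV
#' @param annotations data.frame from [annotate_sequences()].
#' @param path output file.
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write annotated ITS2 intervals as BED
#'
#' BED uses the same 0-based half-open convention as the annotation.
#' @param annotations data.frame from [annotate_sequences()].
#' @param path output file.
#' @export
write_annotation_bed <- function(annotations, path) {
  ok <- annotations[annotations$ok, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tITS2", ok$id, ok$its2_start, ok$its2_end)
  writeLines(lines, path)
  invisible(path)
}
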