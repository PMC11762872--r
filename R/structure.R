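# Secondary-structure prediction: homology modeling by base-pair transfer
# from a template (with a structure-transfer percentage and the >= 50%
# filter), constrained folding by weighted base-pair maximization, and
# helix-architecture analysis against the eukaryote four-helix core.

#' Default nucleotide alignment parameters for structure transfer
#' @return list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
nt_align_params <- function(match = 2, mismatch = -1,
                            gap_open = -5, gap_extend = -2) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

nt_score_matrix <- function(params) {
  syms <- c(NUCS, "N")
  S <- matrix(params$mismatch, 5, 5, dimnames = list(syms, syms))
  diag(S) <- params$match
  S["N", ] <- 0; S[, "N"] <- 0
  S
}

#' Homology-model a target structure from a template
#'
#' Globally aligns the target to the template sequence (affine-gap
#' Needleman-Wunsch) and transfers every template base pair (p, q) whose
#' two positions align to non-gap target positions forming an allowed pair
#' (AU, UA, GC, CG, GU, UG). The transfer percentage is
#' `100 * transferred / template pairs` (denominator: template pairs; see
#' the methods vignette for the alternative).
#'
#' @param target_seq target nucleotide string.
#' @param template one-row data.frame (or list) with `id`, `seq`,
#'   `structure` -- a template with >= 1 base pair.
#' @param params nucleotide alignment parameters ([nt_align_params()]).
#' @param target_id id carried into the result.
#' @return list with `id`, `seq`, `structure` (modeled target),
#'   `transfer_percent`, `template_name`, `n_template_pairs`,
#'   `n_transferred`.
#' @export
transfer_structure <- function(target_seq, template,
                               params = nt_align_params(),
                               target_id = "<target>") {
  target_seq <- normalize_seq(target_seq)
  tpl_seq <- normalize_seq(template$seq)
  if (nchar(target_seq) == 0L || nchar(tpl_seq) == 0L)
    stopf("transfer_structure: empty sequence")
  tpl_pairs <- db_pairs(template$structure, template$id)
  if (nrow(tpl_pairs) == 0L)
    stopf("template '%s' has no base pairs", template$id)
  al <- gotoh_align_chars(chars(tpl_seq), chars(target_seq),
                          nt_score_matrix(params),
                          params$gap_open, params$gap_extend)
  # map template position -> target position (NA where gapped)
  tpl_pos <- cumsum(al$a != SS_GAP)
  tgt_pos <- cumsum(al$b != SS_GAP)
  map <- rep(NA_integer_, nchar(tpl_seq))
  ok <- al$a != SS_GAP & al$b != SS_GAP
  map[tpl_pos[ok]] <- tgt_pos[ok]
  tgt <- chars(target_seq)
  struct <- rep(".", length(tgt))
  n_tr <- 0L
  for (r in seq_len(nrow(tpl_pairs))) {
    i <- map[tpl_pairs[r, 1]]
    j <- map[tpl_pairs[r, 2]]
    if (!is.na(i) && !is.na(j) && is_allowed_pair(tgt[i], tgt[j])) {
      struct[i] <- "("
      struct[j] <- ")"
      n_tr <- n_tr + 1L
    }
  }
  list(id = target_id, seq = target_seq, structure = collapse(struct),
       transfer_percent = 100 * n_tr / nrow(tpl_pairs),
       template_name = template$id,
       n_template_pairs = nrow(tpl_pairs), n_transferred = n_tr)
}

#' Model a target against a template set, keeping the best transfer
#'
#' Returns the result with maximal transfer percentage; ties are broken by
#' template order.
#' @param target_seq target nucleotide string.
#' @param templates data.frame of templates (`id`, `seq`, `structure`).
#' @param params nucleotide alignment parameters.
#' @param target_id id carried into the result.
#' @return a [transfer_structure()] result.
#' @export
select_best_template <- function(target_seq, templates,
                                 params = nt_align_params(),
                                 target_id = "<target>") {
  if (is.null(templates) || nrow(templates) == 0L)
    stopf("select_best_template: empty template list")
  best <- NULL
  for (k in seq_len(nrow(templates))) {
    res <- transfer_structure(target_seq, templates[k, ], params, target_id)
    if (is.null(best) || res$transfer_percent > best$transfer_percent)
      best <- res
  }
  best
}

#' Filter homology-modeling results by transfer percentage
#'
#' The threshold is inclusive: a result at exactly the threshold is kept
#' ("at least 50% structural homology").
#' @param results list of [transfer_structure()] results.
#' @param threshold_percent minimum transfer percentage (default 50).
#' @return list with `kept` and `discarded` (lists of results).
#' @export
filter_by_homology <- function(results, threshold_percent = 50) {
  pct <- vapply(results, `[[`, numeric(1), "transfer_percent")
  keep <- pct >= threshold_percent
  list(kept = results[keep], discarded = results[!keep])
}

#' Constrained fold by weighted base-pair maximization
#'
#' Nussinov-style dynamic program maximizing the summed pair weights
#' (GC = 3, AU = 2, GU = 1 by default) over nested structures, subject to
#' a minimum hairpin loop length and a set of positions forbidden to pair
#' (the central-ring constraint convention). Traceback is deterministic:
#' leaving position i unpaired is preferred on ties, then the smallest
#' pairing partner j.
#'
#' @param seq nucleotide string; N never pairs.
#' @param forbidden integer vector of 0-based positions that must stay
#'   unpaired.
#' @param min_loop minimum number of unpaired positions enclosed by a pair
#'   (j - i - 1 >= min_loop).
#' @param weights named pair weights for GC, AU and GU (each orientation).
#' @return dot-bracket structure string of the same length as `seq`.
#' @export
constrained_fold <- function(seq, forbidden = integer(0), min_loop = 3,
                             weights = c(GC = 3, AU = 2, GU = 1)) {
  if (min_loop < 0) stopf("constrained_fold: min_loop must be >= 0")
  seq <- normalize_seq(seq)
  cs <- chars(seq)
  n <- length(cs)
  if (n == 0L) return("")
  if (length(forbidden) > 0 &&
      (min(forbidden) < 0L || max(forbidden) >= n))
    stopf("constrained_fold: forbidden position outside [0, %d)", n)
  blocked <- rep(FALSE, n)
  blocked[as.integer(forbidden) + 1L] <- TRUE
  wm <- matrix(0, 5, 5, dimnames = list(c(NUCS, "N"), c(NUCS, "N")))
  wm["G", "C"] <- wm["C", "G"] <- weights[["GC"]]
  wm["A", "U"] <- wm["U", "A"] <- weights[["AU"]]
  wm["G", "U"] <- wm["U", "G"] <- weights[["GU"]]
  wpair <- wm[cs, cs, drop = FALSE]  # n x n pair weights
  wpair[blocked, ] <- 0
  wpair[, blocked] <- 0
  pw <- function(i, j) wpair[i, j]
  W <- matrix(0, n + 1L, n + 1L)  # W[i, j+1] = best score on [i, j]
  for (span in seq_len(n)) {
    if (span < min_loop + 2L) next
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      best <- W[i + 1L, j + 1L]  # i unpaired
      ks <- seq(i + min_loop + 1L, j)
      w <- wpair[i, ks]
      ok <- w > 0
      if (any(ok)) {
        cand <- w[ok] + W[i + 1L, ks[ok]] + W[ks[ok] + 1L, j + 1L]
        best <- max(best, cand)
      }
      W[i, j + 1L] <- best
    }
  }
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  eps <- 1e-9
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i <= j) {
      if (j - i < min_loop + 1L) break
      if (W[i, j + 1L] <= W[i + 1L, j + 1L] + eps) {
        i <- i + 1L  # i unpaired preferred on ties
        next
      }
      ks <- seq(i + min_loop + 1L, j)
      found <- FALSE
      for (k in ks) {
        w <- pw(i, k)
        if (w > 0 &&
            abs(w + W[i + 1L, k] + W[k + 1L, j + 1L] - W[i, j + 1L]) < eps) {
          struct[i] <- "("; struct[k] <- ")"
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          found <- TRUE
          break
        }
      }
      if (!found) break  # defensive; should not happen
    }
  }
  collapse(struct)
}

#' Re-fold each exterior helix of a modeled scaffold individually
#'
#' Keeps the scaffold's partition of the sequence into exterior helices
#' and central-ring spacers, and replaces the structure inside each
#' helix span with a constrained-fold optimum for that span. Ring
#' positions stay unpaired and pairs can never cross helix boundaries,
#' so the helix architecture (e.g. the four-helix core) is preserved
#' while each helix is individualized to the target sequence. This is
#' the second phase of the `homology_then_fold` pipeline mode; under a
#' base-pair maximization objective an unpartitioned global re-fold
#' would happily pair across helices, which an energy model would
#' penalize as sterically absurd.
#'
#' @param seq nucleotide string.
#' @param scaffold dot-bracket string (e.g. a homology-modeled
#'   structure) whose outermost pairs delimit the helix spans.
#' @param min_loop minimum hairpin loop length passed to
#'   [constrained_fold()].
#' @return dot-bracket string.
#' @export
refold_helices <- function(seq, scaffold, min_loop = 3) {
  validate_pair(seq, scaffold)
  pairs <- db_pairs(scaffold)
  cs_struct <- rep(".", nchar(seq))
  if (nrow(pairs) == 0L) return(collapse(cs_struct))
  cs <- chars(scaffold)
  depth <- cumsum((cs == "(") - (cs == ")"))
  outer_open <- which(cs == "(" & depth == 1)
  outer <- pairs[pairs[, 1] %in% outer_open, , drop = FALSE]
  for (h in seq_len(nrow(outer))) {
    i <- outer[h, 1]; j <- outer[h, 2]
    # the scaffold's outermost pair stays fixed (it is an allowed pair by
    # construction), so the span remains a single exterior helix even if
    # the interior re-fold splits into several stems
    cs_struct[i] <- "("; cs_struct[j] <- ")"
    if (j - i > 1) {
      sub <- constrained_fold(substr(seq, i + 1, j - 1), min_loop = min_loop)
      cs_struct[(i + 1):(j - 1)] <- chars(sub)
    }
  }
  collapse(cs_struct)
}

#' Positions of the exterior (central) loop of a structure
#'
#' 0-based positions not enclosed by any base pair -- the central ring of
#' an ITS2 structure. Used to derive fold constraints from a
#' homology-modeled structure.
#' @param structure dot-bracket string.
#' @return integer vector of 0-based positions.
#' @export
exterior_loop_positions <- function(structure) {
  cs <- chars(structure)
  depth <- cumsum((cs == "(") - (cs == ")"))
  enclosed <- depth > 0 | cs == ")"
  which(!enclosed & cs == ".") - 1L
}

#' Helix architecture of a secondary structure
#'
#' Decomposes the structure into helices emanating from the exterior
#' (central) loop: each outermost base pair opens one helix, and all pairs
#' nested inside it (across internal loops, bulges and multibranch points)
#' count toward that helix's length. The eukaryote ITS2 core expects four
#' such helices with the third the longest.
#'
#' @param structure dot-bracket string.
#' @return list with `n_helices`, `helix_lengths` (base pairs per helix in
#'   5' to 3' order), `longest_index` (1-based; ties resolved to the
#'   smallest index; NA when there are no helices).
#' @export
analyze_core <- function(structure) {
  pairs <- db_pairs(structure)
  if (nrow(pairs) == 0L)
    return(list(n_helices = 0L, helix_lengths = integer(0),
                longest_index = NA_integer_))
  cs <- chars(structure)
  depth <- cumsum((cs == "(") - (cs == ")"))
  # outermost pairs: '(' at depth 1
  outer_open <- which(cs == "(" & depth == 1)
  outer <- pairs[pairs[, 1] %in% outer_open, , drop = FALSE]
  outer <- outer[order(outer[, 1]), , drop = FALSE]
  lens <- vapply(seq_len(nrow(outer)), function(h)
    sum(pairs[, 1] >= outer[h, 1] & pairs[, 2] <= outer[h, 2]),
    integer(1))
  list(n_helices = nrow(outer), helix_lengths = lens,
       longest_index = which.max(lens))
}

#' Structure reports as TSV
#' @param results list of [transfer_structure()] results (or any list of
#'   records with `id`, `seq`, `structure`, optional `template_name`,
#'   `transfer_percent`).
#' @param path output file.
#' @return the report data.frame, invisibly.
#' @export
write_structure_report <- function(results, path) {
  rows <- lapply(results, function(r) {
    core <- analyze_core(r$structure)
    data.frame(id = r$id,
               template = if (!is.null(r$template_name)) r$template_name else NA,
               transfer_percent = if (!is.null(r$transfer_percent))
                 r$transfer_percent else NA,
               n_helices = core$n_helices,
               longest_index = core$longest_index,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
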