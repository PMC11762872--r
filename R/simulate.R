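# Synthetic data with known ground truth: Yule trees, sequence-structure
# pairs evolving under the 12-state model with compensatory pairing,
# 5.8S-ITS2-28S cistrons with planted boundaries, and template sets at
# controlled divergence.
#
# The root structure encodes the eukaryote ITS2 core: four helices
# emanating from a central ring, the third the longest (default helix
# lengths 6, 8, 14, 5 base pairs). Unpaired sites evolve under the
# substitution model conditioned on staying unpaired; paired sites evolve
# both partners (conditioned on their pairing states) and, if the
# resulting pair is not allowed, the 3' partner is redrawn uniformly from
# the allowed partners of the 5' base (compensatory model). Indels are
# confined to unpaired positions, so the true structures stay well-defined
# under the true alignment.

#' Simulation configuration
#'
#' @param n_taxa number of leaves when a tree is simulated.
#' @param site_count total root length (>= the structural footprint).
#' @param model substitution model ([model_jc12()] by default).
#' @param helix_spec base pairs per core helix, 5' to 3'.
#' @param loop_len hairpin loop length per helix.
#' @param spacer_len unpaired spacer between helices (central ring).
#' @param flank5_len,flank3_len cistron flank lengths (>= 25 gives a full
#'   proximal stem).
#' @param indel_rate indel events per unpaired site per unit branch length.
#' @param seed RNG seed.
#' @return list of class `ss_sim_config`.
#' @export
sim_config <- function(n_taxa = 8, site_count = 120, model = model_jc12(),
                       helix_spec = c(6, 8, 14, 5), loop_len = 4,
                       spacer_len = 3, flank5_len = 60, flank3_len = 60,
                       indel_rate = 0, seed = 42) {
  if (any(helix_spec < 2)) stopf("sim_config: helix lengths must be >= 2")
  footprint <- 2 * sum(helix_spec) + loop_len * length(helix_spec) +
    spacer_len * (length(helix_spec) + 1)
  if (site_count < footprint)
    stopf("sim_config: site_count %d < structural footprint %d",
          site_count, footprint)
  obj <- list(n_taxa = n_taxa, site_count = site_count, model = model,
              helix_spec = helix_spec, loop_len = loop_len,
              spacer_len = spacer_len, flank5_len = flank5_len,
              flank3_len = flank3_len, indel_rate = indel_rate, seed = seed)
  class(obj) <- "ss_sim_config"
  obj
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with exponential waiting times; leaves labeled t1..tn.
#' @param n number of leaves (>= 3).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @return rooted `ape::phylo`.
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = 42) {
  if (n < 3) stopf("simulate_tree requires n >= 3")
  with_seed(seed, {
    tree <- ape::rphylo(n, birth = birth_rate, death = 0)
    tree$tip.label <- paste0("t", seq_len(n))
    tree
  })
}

# root structure string from a helix specification; extra unpaired sites
# are distributed round-robin over the unpaired segments
build_root_structure <- function(config) {
  nh <- length(config$helix_spec)
  # segment layout: spacer, (helix, spacer) * nh; loops inside helices
  seg_unpaired <- c(rep(config$spacer_len, nh + 1),
                    rep(config$loop_len, nh))  # spacers then loops
  extra <- config$site_count -
    (2 * sum(config$helix_spec) + sum(seg_unpaired))
  k <- 0L
  while (extra > 0L) {
    seg_unpaired[k %% length(seg_unpaired) + 1L] <-
      seg_unpaired[k %% length(seg_unpaired) + 1L] + 1L
    extra <- extra - 1L
    k <- k + 1L
  }
  spacers <- seg_unpaired[seq_len(nh + 1)]
  loops <- seg_unpaired[nh + 1 + seq_len(nh)]
  parts <- character(0)
  for (h in seq_len(nh)) {
    parts <- c(parts, strrep(".", spacers[h]),
               strrep("(", config$helix_spec[h]),
               strrep(".", loops[h]),
               strrep(")", config$helix_spec[h]))
  }
  parts <- c(parts, strrep(".", spacers[nh + 1]))
  collapse(parts)
}

sample_root_pair_seq <- function(structure) {
  cs <- chars(structure)
  n <- length(cs)
  seq <- character(n)
  unp <- cs == "."
  seq[unp] <- sample(NUCS, sum(unp), replace = TRUE)
  pr <- db_pairs(structure)
  if (nrow(pr) > 0) {
    types <- c("GC", "CG", "AU", "UA", "GU", "UG")
    probs <- c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)
    pick <- sample(types, nrow(pr), replace = TRUE, prob = probs)
    seq[pr[, 1]] <- substr(pick, 1, 1)
    seq[pr[, 2]] <- substr(pick, 2, 2)
  }
  seq
}

# 4x4 transition matrix among nucleotides of one pairing state, from the
# 12-state P(t) conditioned on the state class being preserved
conditional_nt_matrix <- function(model, t, state,
                                  table = translation_table()) {
  P <- prob_matrix(model, t)
  idx <- match(table$symbol[table$state == state], model$states)
  sub <- P[idx, idx, drop = FALSE]
  sub / rowSums(sub)
  }

sample_markov <- function(cur_idx, Pmat) {
  # cur_idx: integer vector of current states (1..4); row-wise sampling
  cp <- t(apply(Pmat, 1, cumsum))
  u <- stats::runif(length(cur_idx))
  rows <- cp[cur_idx, , drop = FALSE]
  1L + rowSums(rows < u)  # u recycles down columns
}

evolve_edge <- function(node, t, config) {
  # node: list(seq chars, struct chars, keys); returns evolved node
  cs <- node$seq
  st <- node$struct
  if (t > 0) {
    unp <- which(st == ".")
    if (length(unp) > 0) {
      Pu <- conditional_nt_matrix(config$model, t, "unpaired")
      cur <- match(cs[unp], NUCS)
      isn <- is.na(cur)  # N sites do not evolve
      if (any(!isn))
        cs[unp[!isn]] <- NUCS[sample_markov(cur[!isn], Pu)]
    }
    pr <- db_pairs(collapse(st))
    if (nrow(pr) > 0) {
      Pl <- conditional_nt_matrix(config$model, t, "left")
      Pr <- conditional_nt_matrix(config$model, t, "right")
      i5 <- pr[, 1]; i3 <- pr[, 2]
      new5 <- NUCS[sample_markov(match(cs[i5], NUCS), Pl)]
      new3 <- NUCS[sample_markov(match(cs[i3], NUCS), Pr)]
      bad <- !paste0(new5, new3) %in% ALLOWED_PAIRS
      if (any(bad))
        new3[bad] <- vapply(new5[bad], function(b)
          sample(PARTNERS[[b]], 1), character(1))
      cs[i5] <- new5
      cs[i3] <- new3
    }
  }
  node$seq <- cs
  # indels in unpaired positions only
  if (config$indel_rate > 0 && t > 0) {
    p_event <- -expm1(-config$indel_rate * t)
    unp <- which(node$struct == ".")
    del <- unp[stats::runif(length(unp)) < p_event / 2]
    if (length(del) > 0) {
      node$seq <- node$seq[-del]
      node$struct <- node$struct[-del]
      node$keys <- node$keys[-del]
    }
    unp <- which(node$struct == ".")
    nins <- stats::rpois(1, config$indel_rate * t * length(unp) / 2)
    for (z in seq_len(nins)) {
      unp <- which(node$struct == ".")
      if (length(unp) == 0) break
      pos <- sample(unp, 1)  # insert after this unpaired position
      nextkey <- if (pos < length(node$keys)) node$keys[pos + 1]
                 else node$keys[pos] + 1
      key <- (node$keys[pos] + nextkey) / 2
      node$seq <- append(node$seq, sample(NUCS, 1), after = pos)
      node$struct <- append(node$struct, ".", after = pos)
      node$keys <- append(node$keys, key, after = pos)
    }
  }
  node
}

#' Evolve sequence-structure pairs along a tree
#'
#' Builds a root pair from the helix specification and evolves it along
#' every edge under the compensatory 12-state model (see the module
#' header). Ground truth sufficient to score downstream stages is
#' returned: the true alignment (via per-site homology keys), the true
#' per-leaf structures, and the root.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param config an [sim_config()].
#' @return list with `pairs` (data.frame `id`, `seq`, `structure`,
#'   `taxon_name`), `true_alignment` (data.frame `id`, `symbols`, gapped
#'   encoded rows), `root` (list `seq`, `structure`), `tree`, `config`.
#' @export
evolve_pairs <- function(tree, config = sim_config()) {
  with_seed(config$seed, {
    structure <- build_root_structure(config)
    root_seq <- sample_root_pair_seq(structure)
    n_sites <- nchar(structure)
    rootnode <- list(seq = root_seq, struct = chars(structure),
                     keys = as.numeric(seq_len(n_sites)))
    ntip <- length(tree$tip.label)
    nodes <- vector("list", ntip + tree$Nnode)
    tr <- stats::reorder(tree, "postorder")
    root <- tr$edge[nrow(tr$edge), 1]
    nodes[[root]] <- rootnode
    # preorder: reverse postorder edge sweep
    for (e in rev(seq_len(nrow(tr$edge)))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      nodes[[child]] <- evolve_edge(nodes[[parent]], tr$edge.length[e], config)
    }
    pairs <- data.frame(
      id = tree$tip.label,
      seq = vapply(seq_len(ntip), function(i) collapse(nodes[[i]]$seq),
                   character(1)),
      structure = vapply(seq_len(ntip), function(i) collapse(nodes[[i]]$struct),
                         character(1)),
      taxon_name = binomial_names(ntip),
      stringsAsFactors = FALSE)
    # true alignment over the union of homology keys
    all_keys <- sort(unique(unlist(lapply(seq_len(ntip),
                                          function(i) nodes[[i]]$keys))))
    tab <- translation_table()
    rows <- vapply(seq_len(ntip), function(i) {
      enc <- chars(encode_pair(pairs$seq[i], pairs$structure[i], tab,
                               id = pairs$id[i]))
      out <- rep(SS_GAP, length(all_keys))
      out[match(nodes[[i]]$keys, all_keys)] <- enc
      collapse(out)
    }, character(1))
    list(pairs = pairs,
         true_alignment = data.frame(id = tree$tip.label, symbols = rows,
                                     stringsAsFactors = FALSE),
         root = list(seq = collapse(rootnode$seq), structure = structure),
         tree = tree, config = config)
  })
}

# deterministic plausible binomial names for synthetic taxa
binomial_names <- function(n) {
  epithets <- c("albus", "brevis", "cristatus", "dubius", "elegans",
                "fulvus", "gracilis", "hirtus", "incertus", "junceus",
                "kenyensis", "lacustris", "minutus", "nitidus", "obscurus",
                "pallidus", "quadratus", "rotundus", "simplex", "tenuis",
                "undulatus", "validus", "wolffii", "xanthus", "yunnanensis",
                "zonatus")
  ep <- epithets[(seq_len(n) - 1L) %% length(epithets) + 1L]
  suffix <- ifelse(seq_len(n) > length(epithets),
                   letters[(seq_len(n) - 1L) %/% length(epithets)], "")
  paste0("Synthetochytrium ", ep, suffix)
}

#' Fixed synthetic flank motifs for cistron construction
#'
#' 25-nt motifs standing in for the conserved 5.8S end and 28S start.
#' They are arbitrary fixed strings (synthetic; no claim of matching any
#' real rRNA), shared between [make_cistron()] and
#' [default_flank_hmms()] so annotation can recover planted boundaries.
#' @return list with `flank5` and `flank3`.
#' @export
default_flank_motifs <- function() {
  list(flank5 = "GAUCGAUGAAGAACGCAGCGAAAUG",
       flank3 = "UUGACCUCAAAUCAGGUAGGACUAC")
}

#' Default flank profile HMMs
#'
#' Trained from eight slightly perturbed copies (2% substitutions, fixed
#' internal seed) of the synthetic flank motifs, giving sharp but not
#' degenerate emission distributions.
#' @return list with `hmm5` and `hmm3`.
#' @export
default_flank_hmms <- function() {
  motifs <- default_flank_motifs()
  perturb <- function(motif, seed) with_seed(seed, {
    vapply(seq_len(8), function(z) {
      cs <- chars(motif)
      hit <- stats::runif(length(cs)) < 0.02
      cs[hit] <- sample(NUCS, sum(hit), replace = TRUE)
      collapse(cs)
    }, character(1))
  })
  list(hmm5 = build_profile_hmm(perturb(motifs$flank5, 1058), name = "5.8S-end"),
       hmm3 = build_profile_hmm(perturb(motifs$flank3, 2880), name = "28S-start"))
}

#' Build a cistron fragment with planted ITS2 boundaries
#'
#' Concatenates a 5.8S tail (random padding ending in the flank motif),
#' the ITS2 (the pair's sequence), and a 28S head (the motif then random
#' padding). When a flank is shorter than the motif, the motif is
#' truncated on its outer side, so the proximal stem is incomplete
#' downstream.
#'
#' @param pair one-row data.frame (or list) with `id`, `seq`.
#' @param config an [sim_config()] (flank lengths, seed).
#' @param motifs flank motifs ([default_flank_motifs()]).
#' @return list with `record` (one-row data.frame `id`, `seq`,
#'   `taxon_name`) and `truth` (list `its2_start`, `its2_end`, 0-based
#'   half-open, plus `full_flanks`).
#' @export
make_cistron <- function(pair, config = sim_config(),
                         motifs = default_flank_motifs()) {
  with_seed(config$seed + 7919, {
    m5 <- motifs$flank5; m3 <- motifs$flank3
    f5 <- config$flank5_len; f3 <- config$flank3_len
    l5 <- min(nchar(m5), f5)
    tail5 <- substr(m5, nchar(m5) - l5 + 1L, nchar(m5))
    pad5 <- collapse(sample(NUCS, max(0L, f5 - nchar(m5)), replace = TRUE))
    l3 <- min(nchar(m3), f3)
    head3 <- substr(m3, 1L, l3)
    pad3 <- collapse(sample(NUCS, max(0L, f3 - nchar(m3)), replace = TRUE))
    seq <- paste0(pad5, tail5, pair$seq, head3, pad3)
    its2_start <- nchar(pad5) + nchar(tail5)
    list(record = data.frame(
           id = paste0(pair$id, "_cistron"),
           seq = seq,
           taxon_name = if (!is.null(pair$taxon_name)) pair$taxon_name
                        else pair$id,
           stringsAsFactors = FALSE),
         truth = list(its2_start = its2_start,
                      its2_end = its2_start + nchar(pair$seq),
                      full_flanks = f5 >= nchar(m5) && f3 >= nchar(m3)))
  })
}

#' Generate a template set at controlled divergences
#'
#' Evolves the given pairs along single edges of the requested lengths so
#' that expected structure-transfer percentages straddle the 50% filter.
#' @param pairs data.frame with `id`, `seq`, `structure`.
#' @param k number of templates.
#' @param divergence_levels branch lengths cycled over templates.
#' @param seed RNG seed.
#' @param config simulation config (model, indels off for templates).
#' @return data.frame of templates (`id`, `seq`, `structure`).
#' @export
make_template_set <- function(pairs, k = 3, divergence_levels = c(0, 0.2, 0.5),
                              seed = 42, config = sim_config(seed = seed)) {
  if (k < 1) stopf("make_template_set: k must be >= 1")
  config$indel_rate <- 0
  with_seed(seed, {
    out <- vector("list", k)
    for (z in seq_len(k)) {
      src <- pairs[(z - 1L) %% nrow(pairs) + 1L, ]
      d <- divergence_levels[(z - 1L) %% length(divergence_levels) + 1L]
      node <- list(seq = chars(src$seq), struct = chars(src$structure),
                   keys = as.numeric(seq_len(nchar(src$seq))))
      node <- evolve_edge(node, d, config)
      out[[z]] <- data.frame(id = sprintf("tmpl%d_d%s", z, fmt_num(d)),
                             seq = collapse(node$seq),
                             structure = collapse(node$struct),
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
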