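# A complete synthetic study for pipeline-level tests: cistrons built
# from an evolved sequence-structure family, a template set, and (when
# requested) three planted filter failures with known reasons:
#   t2 -> open nomenclature taxon name        (not_binomial)
#   t3 -> 10-nt 5.8S flank                     (truncated_proximal_stem)
#   t4 -> ITS2 replaced by an A/C-only string  (low_structural_homology;
#         A-C combinations can never form allowed pairs)

make_synthetic_study <- function(seed = 42, n = 8, mean_edge = 0.1,
                                 site_count = 120, plant_failures = TRUE,
                                 min_edge = NULL) {
  tree <- simulate_tree(n, seed = seed)
  tree$edge.length <- tree$edge.length * mean_edge / mean(tree$edge.length)
  if (!is.null(min_edge))  # guarantee resolvable internal edges
    tree$edge.length <- pmax(tree$edge.length, min_edge)
  sim <- evolve_pairs(tree, sim_config(n_taxa = n, site_count = site_count,
                                       seed = seed))
  pairs <- sim$pairs
  if (plant_failures) {
    bad_its2 <- ssphylo:::with_seed(seed + 999,
      paste(sample(c("A", "C"), site_count, replace = TRUE), collapse = ""))
    pairs$seq[pairs$id == "t4"] <- bad_its2
  }
  cistrons <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    f5 <- if (plant_failures && pairs$id[i] == "t3") 10 else 60
    cis <- make_cistron(pairs[i, ], sim_config(flank5_len = f5,
                                               seed = seed + i))
    cis$record
  }))
  if (plant_failures)
    cistrons$taxon_name[cistrons$id == "t2_cistron"] <- "Rhizophydium sp."
  templates <- make_template_set(sim$pairs[1, ], k = 3,
                                 divergence_levels = c(0, 0.05, 0.15),
                                 seed = seed + 5)
  kept <- if (plant_failures) setdiff(pairs$id, c("t2", "t3", "t4"))
          else pairs$id
  true_kept_tree <- ape::keep.tip(tree, kept)
  true_kept_tree$tip.label <- paste0(true_kept_tree$tip.label, "_cistron")
  list(tree = tree, sim = sim, cistrons = cistrons, templates = templates,
       kept_ids = paste0(kept, "_cistron"),
       planted_failures = if (plant_failures)
         c(t2_cistron = "not_binomial",
           t3_cistron = "truncated_proximal_stem",
           t4_cistron = "low_structural_homology") else character(0),
       true_kept_tree = true_kept_tree,
       outgroup = "t1_cistron")
}
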