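#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# An 8-taxon Yule tree; ITS2 sequence-structure pairs evolved along it
# under the compensatory 12-state model (four-helix core, third helix
# longest); 5.8S-ITS2-28S cistrons with planted boundaries; a template
# set at three divergence levels. Three records carry planted filter
# failures: t2 has an open-nomenclature name, t3 only 10 nt of 5.8S,
# t4 an A/C-only ITS2 that cannot form allowed base pairs.

suppressMessages(library(ssphylo))
seed <- 42
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- simulate_tree(8, seed = seed)
tree$edge.length <- pmax(tree$edge.length * 0.1 / mean(tree$edge.length), 0.06)
sim <- evolve_pairs(tree, sim_config(n_taxa = 8, site_count = 240, seed = seed))

pairs <- sim$pairs
set.seed(seed + 999)
pairs$seq[pairs$id == "t4"] <- paste(sample(c("A", "C"), 240, TRUE),
                                     collapse = "")
cistrons <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  f5 <- if (pairs$id[i] == "t3") 10 else 60
  make_cistron(pairs[i, ], sim_config(flank5_len = f5, seed = seed + i))$record
}))
cistrons$taxon_name[cistrons$id == "t2_cistron"] <- "Chytridium sp."
cistrons$description <- cistrons$taxon_name
templates <- make_template_set(sim$pairs[1, ], k = 3,
                               divergence_levels = c(0, 0.05, 0.15),
                               seed = seed + 5)

write_fasta(cistrons, file.path(out, "cistrons.fasta"))
write_xfasta(templates, file.path(out, "templates.xfasta"))
write_xfasta(sim$pairs, file.path(out, "true_pairs.xfasta"))
write_newick(tree, file.path(out, "true_tree.nwk"))
jsonlite::write_json(
  list(seed = seed,
       planted_failures = list(t2_cistron = "not_binomial",
                               t3_cistron = "truncated_proximal_stem",
                               t4_cistron = "low_structural_homology"),
       its2_true_intervals = lapply(seq_len(nrow(pairs)), function(i)
         list(id = paste0(pairs$id[i], "_cistron"),
              start = if (pairs$id[i] == "t3") 10L else 60L,
              end = (if (pairs$id[i] == "t3") 10L else 60L) +
                nchar(pairs$seq[i])))),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE)

cat(sprintf("simulated %d taxa, %d sites, %d templates -> %s\n",
            nrow(cistrons), 240, nrow(templates), out))
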