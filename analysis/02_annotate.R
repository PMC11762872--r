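#!/usr/bin/env Rscript
# Stage 2: species-name filter, then ITS2 annotation with the flank
# profile HMMs and the full-proximal-stem filter (25 nt into each flank).

suppressMessages(library(ssphylo))
out <- "results"
cistrons <- read_fasta("results/data/cistrons.fasta")

fs <- filter_species_named(cistrons)
cat(sprintf("species filter: %d kept, %d discarded (%s)\n",
            nrow(fs$kept), nrow(fs$discarded),
            paste(fs$discarded$id, collapse = ", ")))

hm <- default_flank_hmms()
ann <- annotate_sequences(fs$kept, hm$hmm5, hm$hmm3, L = 25)
fa <- filter_annotatable(ann)
cat(sprintf("annotation filter: %d kept, %d discarded\n",
            nrow(fa$kept), nrow(fa$discarded)))
if (nrow(fa$discarded) > 0)
  print(fa$discarded[, c("id", "reason")])

write_annotation_tsv(ann, file.path(out, "annotation.tsv"))
write_annotation_bed(ann, file.path(out, "annotation.bed"))

# extract the annotated ITS2 subsequences for the structure stage
keep <- fs$kept[match(fa$kept$id, fs$kept$id), ]
its2 <- data.frame(id = keep$id, description = keep$taxon_name,
                   seq = substr(keep$seq, fa$kept$its2_start + 1,
                                fa$kept$its2_end),
                   stringsAsFactors = FALSE)
write_fasta(its2, file.path(out, "its2.fasta"))
cat(sprintf("wrote %s and %s\n", file.path(out, "annotation.tsv"),
            file.path(out, "its2.fasta")))
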