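# ssphylo — sequence–structure phylogenetics for the ITS2

`ssphylo` reconstructs phylogenies from the internal transcribed spacer 2
(ITS2) of the rRNA cistron using **both** of its information channels:
the fast-evolving nucleotide sequence and the conserved secondary
structure (four helices around a central ring, helix III the longest).
Every residue is encoded together with its pairing state — unpaired,
paired left `(`, paired right `)` — into a 12-letter alphabet, and all
downstream steps work in that space: 12×12 scoring matrices for
alignment, 12-state substitution models for distances and likelihoods.

It is aimed at molecular systematists who want a transparent, fully
seeded, end-to-end reimplementation of the ITS2 sequence–structure
workflow on their own data or on synthetic benchmarks with known ground
truth.

## What the pipeline does

```
cistrons ──▶ annotate ITS2 (profile HMMs, 25-nt proximal stem)
         ──▶ filter: binomial species name · full proximal stem
         ──▶ structure: template homology modeling (transfer %)
         ──▶ filter: ≥ 50% structural homology
         ──▶ (optional) individualize helices by constrained folding
         ──▶ encode (12 letters) ──▶ progressive 12×12 alignment
         ──▶ NJ / MP / ML trees ──▶ 100-replicate column bootstrap
         ──▶ outgroup rooting ──▶ support mapping (> 50 displayed)
```

Key quantities, in the field's notation:

- **Structure transfer percentage** of a homology model:
  `100 · (transferred pairs) / (template pairs)`, where a template pair
  (p, q) transfers iff both positions align to non-gap target positions
  forming an allowed pair (AU, UA, GC, CG, GU, UG). Records below 50%
  are filtered out.
- **12-state distance correction**:
  `d = −(11/12) · ln(1 − (12/11) · p)` for observed difference
  proportion `p` (saturates at p ≥ 11/12).
- **Bootstrap support** of an internal edge: percentage of 100
  column-resampled replicate trees containing the same bipartition.

A synthetic-data module (first-class, tested code) generates Yule trees,
sequence–structure families evolving with compensatory pairing, cistrons
with planted 5.8S/ITS2/28S boundaries, and template sets at controlled
divergence — with ground truth for every stage.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data with three planted filter failures (an open-nomenclature name, a
truncated 5.8S flank, an unpairable ITS2):

```sh
Rscript analysis/01_simulate.R   # tree, pairs, cistrons, templates
Rscript analysis/02_annotate.R   # HMM annotation + proximal-stem filter
Rscript analysis/03_structure.R  # homology modeling + 50% filter + fold
Rscript analysis/04_align.R      # 12-letter encoding + alignment
Rscript analysis/05_trees.R      # NJ/MP/ML + bootstrap + rooting
```

which prints, stage by stage:

```
species filter: 7 kept, 1 discarded (t2_cistron)
annotation filter: 6 kept, 1 discarded
          id                  reason
2 t3_cistron truncated_proximal_stem
homology filter (>= 50%): 5 kept, 1 discarded
  discarded t4_cistron: transfer 0.0% (template tmpl1_d0)
          id template transfer_percent n_helices longest_index
1 t1_cistron tmpl1_d0              100         4             3
2 t5_cistron tmpl1_d0              100         4             3
3 t6_cistron tmpl1_d0              100         4             3
4 t7_cistron tmpl1_d0              100         4             3
5 t8_cistron tmpl1_d0              100         4             3
aligned 5 sequences into 240 columns
nj: RF to true tree = 0; support = [64, 100]
mp: RF to true tree = 0; support = [100, 71]
ml: RF to true tree = 0; support = [100, 87]
```

Reading this: the three planted failures are discarded with
machine-readable reasons; the five survivors are modeled at 100%
structural homology (their template is a zero-divergence relative), all
keep the four-helix core with helix III longest, and all three tree
methods recover the generator's true topology (Robinson–Foulds distance
0), with bootstrap support values mapped at the internal nodes of the
rooted trees. Artifacts (annotation TSV/BED, xfasta structures, encoded
alignment, PHYLIP distances, Newick trees with and without the > 50
display rule) are written under `results/`.

The same machinery is available in one call:

```r
library(ssphylo)
cfg <- run_config(cistrons = "results/data/cistrons.fasta",
                  templates = "results/data/templates.xfasta",
                  structure_mode = "homology_then_fold",
                  tree_methods = c("nj", "mp", "ml"),
                  bootstrap_B = 100, outgroup = "t1_cistron",
                  seed = 42, out_dir = "results/run")
res <- run_pipeline(cfg)
res$manifest   # per-record kept/discarded ledger with reasons
```

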