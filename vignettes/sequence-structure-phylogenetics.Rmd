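---
title: "Sequence-structure phylogenetics of the ITS2: models and methods"
author: "ssphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-structure phylogenetics of the ITS2: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssphylo)
```

## The problem

The internal transcribed spacer 2 (ITS2) of the rRNA cistron evolves fast
at the sequence level while its secondary structure — four helices
emanating from a central ring, the third helix the longest — is conserved
across eukaryotes. Phylogenetic methods that score only the nucleotide
channel discard the conserved structural signal; methods that fuse both
channels encode each nucleotide together with its pairing state (unpaired,
paired left, paired right) into a 12-letter alphabet and work with 12×12
scoring matrices and 12-state substitution models throughout alignment and
tree reconstruction.

`ssphylo` implements that approach as a staged, fully seeded pipeline:

1. **Annotation** — delimit the ITS2 inside a 5.8S–ITS2–28S fragment with
   small profile HMMs for the flanking rRNA ends, and extend the region by
   the proximal-stem convention (25 nt into each flank).
2. **Filters** — keep only records with a clean binomial species name, a
   full proximal stem, and at least 50% structural homology to a template.
3. **Structure** — homology modeling by base-pair transfer from template
   structures, optionally followed by individualizing each homologous
   helix through constrained folding.
4. **Encoding** — translate each sequence–structure pair into the
   12-letter alphabet.
5. **Alignment** — progressive multiple alignment under a 12×12 scoring
   matrix with affine gaps.
6. **Trees** — neighbor-joining on corrected 12-state distances, Fitch
   parsimony, and maximum likelihood by Felsenstein pruning; 100
   column-bootstrap pseudo-replicates; outgroup rooting; support mapping.

Because public ITS2 data require network retrieval, the package ships a
first-class synthetic-data module that generates every input with known
ground truth, so each stage can be scored exactly.

## Annotation model

The two flanks are modeled as profile HMMs with match, insert, and delete
states and position-independent transition probabilities. A builder trains
match emissions from an ungapped motif alignment by maximum likelihood
with a pseudocount of 1 per nucleotide. Search is *glocal*: the model must
be traversed from its first to its last column (entry and exit through
delete chains are allowed, at a cost), while sequence outside the hit is
free; scores are Viterbi log-odds against a uniform background, so an
empty hit scores 0 and the default acceptance floor is 0. The ITS2 is the
region strictly between the 5.8S-end hit and the 28S-start hit; the
proximal interval extends it by up to `L = 25` nt on each side, and
`full_proximal_stem` is true only when both extensions are untruncated.
We use the 25-nt flank convention for the proximal stem; the alternative
reading (only the paired region of the 5.8S/28S interaction) is not
implemented.

Two tunables deserve comment. The **delete transitions** default to
`md = 0.10`, `dd = 0.70`, deliberately cheap so that a fragment carrying
only part of a flank (say 10 of 25 nt) still aligns and is reported as
*truncated* rather than failing outright. The cost of this sensitivity is
specificity: on some inputs a partial spurious hit inside the spacer can
clear the floor, so truncated fragments are occasionally annotated with a
plausible-looking but wrong 5.8S boundary. The conservative filters
downstream (and the Viterbi score itself, which is far lower for spurious
hits) are the mitigation; raising `floor` trades the two error modes. The
**strand** is taken as given; reverse-complement scanning is not on by
default.

## Structure prediction

**Homology modeling.** The target is aligned to the template sequence by
global affine-gap Needleman–Wunsch (match 2, mismatch −1, gap open −5,
gap extend −2 by default). A template pair (p, q) transfers to target
positions (i, j) when both positions align to non-gap target columns and
the target nucleotides form an allowed pair (AU, UA, GC, CG, GU, UG).
The *structure transfer percentage* is 100 × transferred / template
pairs; the template-pair denominator is our explicit choice (the
alternative — fraction of target positions receiving structure — changes
little and is not exposed). The ≥ 50% filter is inclusive. Note that
"unrelated template" does not mean 0%: a random aligned position pair is
an allowed pair with probability ≈ 6/16, so scrambled or unrelated
templates land at chance level around 35–45% — below the filter, which is
what matters.

**Constrained folding.** The second prediction mode maximizes the summed
weights of nested base pairs (GC = 3, AU = 2, GU = 1, a stacking-free
stand-in for a full thermodynamic model), subject to a minimum hairpin
loop of 3 nt and a set of forbidden positions (the central-ring
convention: ring positions may not pair). The traceback is deterministic:
leaving a position unpaired is preferred on ties, then the smallest
pairing partner. The DP is verified against exhaustive enumeration of all
nested structures on short sequences.

**Individualizing helices.** In the two-phase mode
(`homology_then_fold`), each exterior helix span of the modeled scaffold
is re-folded independently, with the scaffold's outermost pair kept
fixed. A single global re-fold is *not* used: under a pair-counting
objective it will happily pair the 5′ arm of helix I with the 3′ arm of
helix IV, collapsing the four-helix core into one absurd mega-helix that
an energy model would never produce. Even with the partition kept, the
pair-count objective packs diverged loop regions with taxon-specific
pairs, which adds noise to the structure channel; consequently backbone
recovery claims in the tests are made in pure homology mode, and the
two-phase mode is asserted to preserve the four-helix architecture.

**Helix-core report.** Helices are the outermost pairs of the structure;
all pairs nested inside an outermost pair (across bulges, internal loops,
and multibranch points) count toward that helix's length. The eukaryote
core check is then simply `n_helices == 4` with `longest_index == 3`.

## Encoding

Each (nucleotide, pairing state) combination maps to one of 12 letters:
unpaired A,C,G,U → `A,C,G,U`; paired-left → `B,D,H,V`; paired-right →
`E,F,I,W`. The assignment is arbitrary but fixed and versioned
(`ssphylo-1`), and every downstream score, distance and likelihood is
invariant under relabeling (property-tested). `N` is allowed only
unpaired and encodes as the wildcard `X`, which is excluded from distance
and likelihood counts. Decoding validates that the implied bracket string
is balanced, so encode/decode is an exact round trip on valid input.

## Alignment

The 12×12 score of two symbols is the sum of a nucleotide term (+2 same /
−1 different) and a pairing-state term (+2 same / −2 different), keeping
the two information channels separately tunable; gap open −8, gap extend
−2, terminal gaps penalized like internal ones. An alternative matrix can
be loaded from TSV. Pairwise alignment is the Gotoh three-matrix DP,
verified against brute-force enumeration of all global alignments at
short lengths. The guide tree is NJ on pairwise fractional-identity
distances (d = 1 − identity); profiles are merged in postorder with
profile–profile column scores equal to the mean pairwise symbol score
over non-gap symbols, and "once a gap, always a gap". On low-divergence
simulated families with loop-confined indels the aligner recovers ≥ 95%
of true homologous column pairs.

## Distances, trees, support

The observed proportion of differing sites p (gap and wildcard columns
excluded pairwise) is corrected with the 12-state equal-rates closed form

d = −(11/12) · ln(1 − (12/11) · p),

which saturates at p ≥ 11/12. Neighbor-joining follows Saitou–Nei with
the Studier–Keppler criterion; negative branch lengths are clamped to
zero with the deficit moved to the sister edge (their sum is preserved),
and Q-ties break deterministically by the smallest label pair. NJ is
exact on additive matrices (tested on random trees up to 10 taxa).

Fitch parsimony works on 12-state bitmask sets with gaps as missing data;
the unrooted tree is evaluated rooted at its first tip, making every
combine binary and the count exact (verified against brute force over
internal assignments and against an independent implementation). MP
search enumerates all topologies up to 8 taxa (Fitch is cheap) and uses
first-improvement NNI from the NJ tree beyond.

Likelihoods use Felsenstein pruning with per-node scaling; JC12 has a
closed-form transition matrix, and GTR12 is built from 66
exchangeabilities and a stationary distribution via eigendecomposition of
the π-symmetrized generator, with exchangeabilities estimable from the
data by direct likelihood maximization on a fixed tree (frequencies from
counts). Branch lengths are optimized per edge by Brent search to
tolerance 1e-6. ML topology search enumerates all topologies up to **6**
taxa and uses NNI beyond; the enumeration bound is lower than parsimony's
because every candidate topology needs full branch-length optimization,
which is two orders of magnitude more expensive than a Fitch pass at this
implementation's speed. Bootstrap replicates resample encoded alignment
columns with replacement — sequence and structure jointly, since the
encoding fuses them — under an explicit seed; ML replicate trees use NNI
search only. Support of an internal edge is the percentage of replicates
containing the same bipartition; all values are stored exactly, and the
convention of displaying only values above 50 is applied at write time
only. Rooting places the root at the midpoint of the edge separating a
monophyletic outgroup.

## The synthetic-data generator

The generator is the package's study condition, not a tuning dial. The
root structure realizes the four-helix core from a helix specification
(default 6, 8, 14, 5 base pairs — third longest), hairpin loops of 4 nt,
central-ring spacers of 3 nt, and round-robin padding of any extra sites
across the unpaired segments. Root nucleotides are uniform at unpaired
sites; pair types are drawn GC/CG 30% each, AU/UA 15%, GU/UG 5%.

Along each edge, unpaired sites evolve under the 12-state model
*conditioned on preserving the site's structural state* (the renormalized
4×4 block of P(t)): a site's pairing state is fixed by the true structure,
so unconditional 12-state transitions would be structurally meaningless.
Paired sites evolve both partners under their respective conditionals,
and when the resulting pair is not allowed the 3′ partner is redrawn
uniformly from the allowed partners of the 5′ base — the compensatory
mechanism that keeps structure conserved while sequence diverges. Two
consequences are documented rather than hidden: the realized per-site
process is not exactly JC12 (the JC12 distance correction is therefore
mildly misspecified for generator data — harmless for topology recovery,
which is what the tests assert), and substitution-count expectations used
in tests are computed from the generator's own conditional matrices.

Indels (off by default) are confined to unpaired positions, so true
structures remain well-defined; per-site homology keys record the true
alignment exactly, including inserted columns. Cistrons concatenate a
5.8S tail ending in a fixed 25-nt synthetic motif, the ITS2, and a 28S
head starting with a second motif; truncating a flank below 25 nt plants
a proximal-stem failure. The default flank HMMs are trained from eight
2%-perturbed copies of those motifs. Template sets are produced by
evolving a pair along single edges of chosen lengths, so expected
transfer percentages straddle the 50% filter. Taxon names are synthetic
binomials; planted filter failures use an open-nomenclature name, a
10-nt flank, and an A/C-only ITS2 (A–C combinations can never pair, so
its transfer percentage is ~0).

What the generator does *not* emulate: real chytrid base composition,
rate heterogeneity across sites, pseudoknots, structurally misassigned
templates, and alignment-breaking structural rearrangements. Passing
tests therefore demonstrate correctness of the algorithms under the
stated model, not that the pipeline resolves any particular real clade.

## Numerical choices and problem sizes

Floating-point ties in DP tracebacks use an absolute epsilon of 1e-9 on
integer-valued score sums. Branch-length optimization uses Brent on
[0, 10] with tolerance 1e-6; likelihood scaling is per node. All
stochastic steps take an explicit integer seed and restore the caller's
RNG state. The test and acceptance workloads are sized for a single CPU:
oracle equivalences run at the sizes where exhaustive enumeration is
exact (alignments ≤ 6 symbols, folds ≤ 12 nt, parsimony ≤ 6 taxa,
likelihood ≤ 5 taxa, NJ ≤ 10 taxa); the recovery study uses a fixed
8-taxon tree with edges drawn from [0.05, 0.3], 2000 sites and 100
replicates, and bootstrap comparisons use 100 pseudo-replicates at 500
versus 4000 sites. With that design NJ recovers the true topology in
(nearly) all replicates and mean true-clade support does not decrease
with sequence length.

## Known limitations

- The folding objective is weighted base-pair maximization, not a
  thermodynamic model; its global optimum on diverged loops is noisy, and
  the two-phase pipeline mode therefore individualizes helices within the
  homologous scaffold instead of re-folding globally.
- Annotation favors sensitivity on truncated flanks; spurious partial
  hits above the floor are possible on degenerate inputs.
- ML topology search is exhaustive only to 6 taxa; beyond that NNI
  hill-climbing can stop in local optima, and replicate trees in the ML
  bootstrap always use NNI.
- GTR12 estimation optimizes 66 exchangeabilities by generic
  quasi-Newton search; on small alignments it is slow and weakly
  identified, and JC12 is the default everywhere.
- No Bayesian inference, no Γ rate heterogeneity, no pseudoknots, and no
  claim of bit-compatibility with 4SALE, ProfDistS, RNAstructure, PAUP*
  or phangorn output formats beyond standard FASTA/Newick.
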