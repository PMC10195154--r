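---
title: "Models and methods: ohnolog retention and loss after whole-genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ohnolog retention and loss after whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The problem

A whole-genome duplication (WGD) creates a redundant copy of every gene.
Most of the duplicate pairs (ohnologs) subsequently lose one copy, but a
substantial fraction is retained over very long times, and the retention
pattern carries information about the selective forces at work — dosage
constraints in particular. In a clade of species that radiated shortly
after a shared WGD (the motivating system is a complex of morphologically
cryptic ciliate species), every extant genome is an independent replay of
the same loss process, so one can ask *when* losses happened, *which*
copy was lost, and *what* biases the outcome.

`paralogon` implements the full analysis chain for this setting:

1. within-genome detection of WGD anchor pairs and their assembly into
   **paralogons** (colinear duplicated segments), with per-locus
   retained/lost calls and reconstruction of the pre-WGD gene order;
2. cross-species orthology that respects the WGD copy structure
   (1-to-1, 1-to-2 and 2-to-2 relations, scaffold orthology scores,
   gene-tree ortholog groups, paralogon chains);
3. Dollo-parsimony mapping of losses onto the species tree with explicit
   missing-data rules, survival curves and exponential decay fits;
4. statistics of parallel vs. reciprocal loss, expression-biased loss,
   retention vs. expression and functional category;
5. gene-conversion detection as changepoints in Ks along paralogons, and
   recent single-gene-duplication (SGD) calling;
6. a MAPS-style subtree vote locating the WGD on branches of a ladder
   quartet.

All stages are validated against a forward simulator
(`simulatePostWGD()`) that emits every input the pipeline consumes plus
complete ground truth.

## The simulator

`simConfig()` holds the generative model. Time is measured in expected
synonymous substitutions per synonymous site (Ks), so that divergence
and time share one scale; each lineage accumulates substitutions at rate
`t/2` per branch of length `t`, which makes the pairwise Ks of two
ohnologs equal to their tree distance since the WGD.

* **Species tree.** An ultrametric ingroup tree whose splits all fall in
  the oldest 45% of the crown age — a radiation shortly after the WGD,
  with short internal and long terminal branches. Up to two pre-WGD
  outgroups attach at 1.5 and 2 times the WGD depth. The WGD itself sits
  a short stem (`wgd_stem`, default 0.1 Ks) *above* the crown. This stem
  matters: if the WGD coincided exactly with the first speciation, the
  four gene lineages (two copies in each primary clade) would all
  diverge at the same instant and copy identity across the deepest split
  would be unidentifiable in principle — no orthology method could beat
  chance. A short positive stem reflects the biology (the WGD shortly
  predates the radiation) and restores identifiability. Losses on the
  stem are shared by all species; such pairs are single-copy at the
  crown and excluded from the crown pair count, mirroring how the
  per-node survival reference is defined.
* **Copy loss.** Along a branch of length `t`, a still-duplicated pair
  loses one copy with probability `1 - exp(-h t)`, with hazard
  `h = base_loss_rate * exp(-expr_beta * logE) * category_effect`,
  where `logE = log10(FPKM + 0.1)` of the pair. Defaults
  (`base_loss_rate = 0.7` per Ks at unit depth, `expr_beta = 0.25`)
  give leaf retention near one half with a visible expression bias.
  Loss is instantaneous copy deletion — the analysis scores intact
  presence/absence, so pseudogene intermediates are not modelled.
* **Which copy.** A per-pair asymmetry state `z` performs a Brownian
  walk on the logistic scale at rate `predetermination_drift`
  (inherited across speciations); at a loss event copy A is chosen with
  probability `plogis(z + expression_copy_bias * (logE_B - logE_A))`.
  With `predetermination_drift = 0` and `expression_copy_bias = 0`
  (the default for the latter) the choice is exactly symmetric, so
  parallel and reciprocal losses are equally frequent — the documented
  null. Positive drift makes the same copy progressively more likely to
  be lost in independent lineages, and the parallel fraction grows with
  the WGD-to-speciation distance; a positive `expression_copy_bias`
  loads the loss onto the currently lower-expressed copy.
* **Expression.** Ancestral FPKM is log-normal (`meanlog 2`,
  `sdlog 1.5`, natural log); each surviving copy drifts
  multiplicatively (`expr_drift`, default 0.3 per sqrt-Ks).
* **Sequences.** CDS are uniform random sense codons (100–300 codons);
  substitutions arrive as Poisson events, synonymous events at the
  branch rate and nonsynonymous events scaled by `omega` (default 0.05,
  strong purifying selection). This codon-position scheme is simpler
  than a full codon model but is calibrated: the package's own
  counting estimator recovers the generative Ks within ~4% at Ks 0.3
  (an upward bias of order 10% appears near Ks 1 as the Jukes–Cantor
  correction's assumptions degrade).
* **Structural events.** Gene-conversion tracts (Poisson per paralogon,
  geometric length, copy A overwrites copy B), single-gene duplications
  (copy inserted next to its source), and translocations (gene moved to
  a random position). `plantSGDs()` additionally plants duplicates of a
  chosen age for controlled validation.
* **Lineage rate variation.** `rate_sigma` (default 0) draws one
  lognormal multiplier per branch shared by *all* processes, coupling
  loss hazard and sequence divergence — the mechanism behind the
  negative retention-vs-Ks correlation across species.

What the simulator does **not** emulate: indels (alignments are still
exercised, but simulated homologs are length-conserved), assembly and
annotation error, pseudogenes, GO structure (categories are flat
labels), expression measurement noise, and micronuclear biology. Tests
passing on simulations therefore demonstrate the pipeline's correctness
under its stated model, not robustness to real-data artefacts.

## Homology and divergence

BLAST is replaced by exact global alignment (BLOSUM62, affine gaps
10/0.5) behind a 5-mer prefilter (pairs sharing at least two words are
aligned; words occurring in more than 50 sequences are masked) and a
score floor of 50, below which unrelated random proteins fall. Ks/Ka
uses Nei–Gojobori-style counting: per-codon site counts, all-pathway
difference averaging (stop-containing paths skipped), and Jukes–Cantor
correction with an explicit saturation flag at p >= 3/4. Gene trees are
neighbour-joining; in the cross-species pipeline they default to
*nucleotide* distances because at `omega = 0.05` the protein carries
almost no signal at the copy split.

## Paralogons

Within-genome reciprocal best hits (RBH) are anchor pairs; anchors are
chained into colinear blocks (rank gap <= 5 on both scaffolds, one
orientation per block, >= 3 anchors), blocks sharing a scaffold pair
fuse into paralogons (gap <= 10). A chain whose two segments overlap on
one scaffold is a tandem array, not a duplicated-segment pair, and is
discarded. In-span non-anchor genes become SINGLE_COPY loci (or
RETAINED_BOTH when a family partner sits across the block); genes
outside every block stay unassigned rather than being called lost.
The published pipeline this follows does not state its window
parameters; the defaults here were chosen for >= 95% truth recovery on
simulations and are exposed as arguments. Ancestral reconstruction
picks one seeded-random representative per retained locus and can
append loose anchors and unassigned genes so that each surviving gene
is represented exactly once.

## Orthology across species

Candidates come from within-family cross-species best hits, typed by
family copy counts. Because speciation follows the WGD closely,
per-gene and even per-family signals are weak; the block-level signal
is decisive (this is the same observation that motivates block-wise
orthology in the source analyses). `copyScaffoldScores()` aggregates,
over all 2-to-2 families on a scaffold quadruple, the distance contrast
`d(a1,b2) + d(a2,b1) - d(a1,b1) - d(a2,b2)`, making one high-confidence
correspondence decision per quadruple; 2-to-2 pairings and 1-to-2
resolutions then follow the scaffold scores (ties stay unresolved and
are logged). Ortholog groups are grown from gene-tree sister pairs,
absorbing sibling subtrees while every leaf adds a new species; chains
of paralogons are extracted greedily from the heaviest graph edges,
each paralogon joining at most one chain. Rooting prefers a clean
clade split and falls back to a topological midpoint (the rooting used
only to orient group growth).

## Loss mapping and decay

States BOTH/ONE/NA are reconstructed post-order under zero gain
probability: any child BOTH forces BOTH; (ONE, ONE) gives ONE;
(NA, BOTH) -> BOTH, (NA, ONE) -> NA, (NA, NA) -> NA. Loss events sit on
branches from BOTH parents to ONE children; on complete data this
equals exhaustive minimum-loss Dollo enumeration (tested). Survival at
a node is its BOTH count over the root count, plotted against distance
from the root.

A known limitation, documented deliberately: at internal nodes with few
descendants, parsimony survival is biased downward — a cherry both of
whose leaves later lose a copy (in either pattern) is falsely
reconstructed as ONE. On radiation-shaped trees this bias mimics a fast
early phase, and a two-phase mixture can win an information-criterion
comparison even when the generative hazard is constant. Decay-recovery
validation therefore fits the simulator's exact node counts
(`survivalFromTruth()`); the parsimony route still recovers the rate
itself within a few percent. Model comparison uses AICc with a
delta > 2 threshold for preferring the two-phase model.

Parallel/reciprocal classification requires independent losses (shared
ancestral-branch events are excluded); the trend statistic is the
Pearson correlation of the parallel fraction with the WGD-to-speciation
distance. Expression-biased loss reports both the loss-rate enrichment
among the most expression-divergent pairs (chi-square) and the fraction
of losses hitting the ortholog of the lower-expressed copy (one-sample
proportion test with continuity correction), the latter both overall
and within the top-divergence stratum, where the heritable component of
expression divergence dominates and the bias is strongest.

## Retention analyses

Expression level is `log10(FPKM + 0.1)` (base 10 chosen as the FPKM
convention; configurable). Cross-species retention of an outgroup gene
is the number of ingroup species retaining both copies over the number
with at least one ortholog; genes with no ortholog are excluded, not
scored zero. Binned profiles use 14 equal-count quantile bins with
normal-approximation 95% intervals. Category bias reports per-category
means per clade, their cross-clade Pearson correlation, and an
expression-controlled enrichment by permuting retention within 5
expression strata (assumption-free, rather than a regression model),
with Benjamini–Hochberg adjustment across categories.

## Conversion and single-gene duplications

Ks series over retained loci follow the ancestral order, blocks
concatenated. Changepoints come from exact penalized optimal
partitioning under a Gaussian mean cost (minimum segment 3). The
default penalty is `4 sigma^2 log n` with sigma estimated robustly from
successive differences; the constant was calibrated on null profiles so
that downstream conversion flagging keeps its false-positive rate at or
below the segment-test level (~5%) while retaining essentially full
power for tracts of >= 5 loci at a >= 50% Ks drop. Only downward
segments, significantly low by a one-sided Wilcoxon test, are flagged
as conversion candidates.

SGD calling applies the four filters in order: within-genome RBH;
removal of pairs already annotated as WGD-derived (block-assigned
anchors and retained-both loci); both genes inside a paralogon
(per-scaffold paralogon spans with a 5-rank slack, since block edges
are fuzzy by the chaining gap); and Ks below 1.0. Per-filter removal
counts are attached to the result. The method targets *recent*
duplications by construction — a duplication as old as the WGD is
indistinguishable from a relocated ohnolog, and the same RBH logic that
finds the pair can occasionally be captured by an unusually conserved
ohnolog instead; validation therefore plants duplicates of known recent
age.

## WGD placement

For a ladder quartet (three clade taxa plus one out-of-clade taxon),
each gene tree is pruned to the quartet (dropped unless every taxon
keeps a copy), rooted on the out-taxon, and its deepest species-overlap
duplication node (children's species sets intersect) is mapped to a
ladder branch; percentages over subtrees are banded at >= 50 / >= 25 /
< 25. Species-overlap is a deliberate distillation of duplication
mapping to the quartet case; no null-percentile machinery is attempted.

## Determinism and problem sizes

Every stochastic step flows from a single integer seed; reruns are
byte-identical, ties break lexicographically by identifier and are
logged (`options(paralogon.verbose = TRUE)`). The validation suite runs
entirely on simulated data at desk scale — typical sizes are 2,000 to
5,000 pairs for loss-dynamics statistics, 250 to 600 genes for
sequence-level stages, and 50 replicates for calibration-style checks —
sizes chosen as the package's own balance between statistical power
and turnaround, and stated here so results can be regenerated exactly.
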