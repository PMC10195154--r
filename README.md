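# paralogon

Ohnolog retention and loss dynamics after whole-genome duplication.

After a whole-genome duplication (WGD), every gene exists in two copies
(*ohnologs*). Most pairs revert to single copy; the survivors, and the
order in which losses happen across a clade of descendant species,
record the selective forces — dosage constraint above all — that oppose
gene loss. `paralogon` is an R package for this analysis in clades that
radiated shortly after a shared WGD (the motivating system is a complex
of cryptic *Paramecium*-like ciliate species): it reconstructs
**paralogons** (colinear duplicated segments) inside each genome, calls
retained and lost duplicates, resolves copy-aware orthology across
species, maps losses onto the species tree, and quantifies the biases
that shape retention.

## The models at its core

* **Loss mapping.** Per-pair states (BOTH / ONE / NA) at the leaves are
  propagated to ancestors by Dollo parsimony — the probability of
  duplicate *gain* is zero — with explicit missing-data rules
  (NA ∨ BOTH → BOTH, NA ∨ ONE → NA, NA ∨ NA → NA). A loss is assigned
  to every branch from a BOTH parent to a ONE child. Survival at a node
  is `n_BOTH(node) / n_BOTH(root)`, and its decay with distance *d*
  from the WGD (in Ks units) is fitted as S = exp(−λd), compared by
  AICc against the two-phase mixture
  S = p·exp(−λ₁d) + (1−p)·exp(−λ₂d).
* **Divergence.** Ks and Ka by Nei–Gojobori-style counting with
  Jukes–Cantor correction, behind protein-guided codon alignment.
* **Paralogon detection.** Within-genome reciprocal best hits chained
  into colinear blocks (monotone rank mapping, bounded gaps), fused
  into paralogons, with per-locus status calls and seeded-random
  reconstruction of the pre-WGD gene order.
* **Copy-aware orthology.** Within-family best hits typed 1-to-1 /
  1-to-2 / 2-to-2; scaffold orthology scores (including block-level
  aggregated distance contrasts) resolve which copy corresponds to
  which; gene-tree ortholog groups and a weighted paralogon graph chain
  paralogons across species.
* **Bias statistics.** Parallel vs. reciprocal loss and its trend with
  WGD-to-speciation distance; expression-biased loss (one-sample
  proportion test with continuity correction); retention vs. expression
  in 14 quantile bins; per-category retention with an
  expression-stratified permutation test.
* **Conversion and SGDs.** Gene-conversion tracts as downward
  mean-shifts in Ks along paralogons (exact penalized segmentation);
  recent single-gene duplications by ordered RBH → non-anchor →
  inside-paralogon → Ks < 1 filters.
* **WGD placement.** A MAPS-style vote: ladder-quartet subtrees of the
  gene trees, species-overlap duplication nodes mapped to branches.

A forward simulator (`simulatePostWGD()`) generates complete post-WGD
clades — tree, sequences, expression, losses, conversion tracts,
single-gene duplications — together with ground truth for every event,
and backs the entire test suite.

## Worked example

Simulate a 13-species post-WGD clade plus one pre-WGD outgroup, map the
losses, and fit the survival decay:

```r
library(paralogon)

cfg <- simConfig(n_genes = 2000, n_scaffolds = 10, n_ingroup = 13,
                 n_outgroup = 1, sequences = FALSE,
                 sgd_rate = 0, translocation_rate = 0, conversion_rate = 0)
sim <- simulatePostWGD(cfg, seed = 1)
sim
#> WGDSimulation: 14 leaf genomes, 2000 ancestral pairs
#>   mean leaf retention: 0.571

tr  <- wgdSubtree(speciesTree(sim))
anc <- ancestralStates(tr, presenceFromTruth(sim))
sv  <- survivalCurve(anc, tr)
fitDecay(sv$distance, sv$survival)[c("model", "lambda")]
#> $model
#> [1] "one_phase"
#> $lambda
#> [1] 0.5745814
```

The fraction of pairs retaining both copies varies between 0.55 and
0.59 across the 13 species here, and the per-node survival decays as a
single exponential whose rate reflects the configured loss hazard
(0.7 per unit Ks, attenuated by the expression effect). Retention rises
with the outgroup's expression level, exactly as the binned profile
shows:

```r
rr <- crossSpeciesRetention(presenceFromTruth(sim))
og <- leafGenomes(sim)[["out1"]]
ex <- expressionLevel(og$fpkm[match(paste0("out1_", rr$gene_id),
                                    og$gene_id)])
head(binnedRetention(ex, rr$rate, 14)[, c("bin", "mean_rate", "n")], 4)
#>   bin mean_rate   n
#> 1   1 0.4604550 142
#> 2   2 0.5121033 143
#> 3   3 0.5029586 143
#> 4   4 0.5422270 143
```

The lowest-expression bin retains 46% of pairs, the profile climbs with
expression level (Spearman rho ≈ 0.98 over the 14 bins at the default
expression effect). Sequence-level stages (paralogon detection,
orthology, conversion, SGD calling) run from `crossSpeciesPipeline()`
on genomes simulated with `sequences = TRUE`; see the vignette for the
models and parameter choices.

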