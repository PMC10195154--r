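Package: paralogon
Title: Ohnolog Retention and Loss Dynamics after Whole-Genome Duplication
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the fate of paralog pairs created by a
    whole-genome duplication (ohnologs) across a clade of descendant
    genomes. Detects within-genome WGD anchor pairs and assembles them
    into paralogons (colinear duplicated segments), calls retained and
    lost duplicates, reconstructs the pre-WGD ancestral gene order, maps
    losses onto a species tree by Dollo parsimony with explicit
    missing-data rules, fits exponential survival decay to ancestral
    retention rates, quantifies parallel versus reciprocal losses and
    expression-biased loss, relates retention to expression level and
    functional category, detects gene-conversion tracts as changepoints
    in synonymous divergence along paralogons, calls recent single-gene
    duplications, and places WGD events on branches by a gene-tree
    subtree vote. Includes a forward simulator of post-WGD genome
    evolution that emits all pipeline inputs together with ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Biostrings,
    minpack.lm,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
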