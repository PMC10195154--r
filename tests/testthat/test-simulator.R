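# Forward simulator: tree shape, ancestral genome, WGD, loss process,
# truth replay and on-disk round trips.

fastCfg <- function(...) {
  simConfig(n_genes = 100, n_scaffolds = 4, n_ingroup = 3, n_outgroup = 0,
            depth = 1, wgd_stem = 0, sequences = FALSE, sgd_rate = 0,
            conversion_rate = 0, translocation_rate = 0, ...)
}

test_that("species tree generation is ultrametric, rooted and seeded", {
  cfg <- simConfig(n_ingroup = 2, n_outgroup = 0, depth = 1, wgd_stem = 0)
  tr <- simulateSpeciesTree(cfg, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(sort(tr$edge.length), c(1, 1))

  cfg4 <- simConfig(n_ingroup = 4, n_outgroup = 2, depth = 1, wgd_stem = 0.1)
  tr4 <- simulateSpeciesTree(cfg4, seed = 2)
  d <- ape::node.depth.edgelength(tr4)
  ing <- match(attr(tr4, "ingroup"), tr4$tip.label)
  expect_true(ape::is.rooted(tr4))
  # every ingroup root-to-leaf distance equals the full tree height
  expect_equal(d[ing], rep(max(d), length(ing)), tolerance = 1e-9)
  # crown of the ingroup sits depth - stem above the leaves
  crown_h <- max(d) - d[attr(tr4, "wgd_node")]
  expect_equal(unname(crown_h), 0.9, tolerance = 1e-9)

  t1 <- simulateSpeciesTree(simConfig(n_ingroup = 13), seed = 7)
  t2 <- simulateSpeciesTree(simConfig(n_ingroup = 13), seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("ancestral genome layout and expression distribution", {
  cfg <- simConfig(n_genes = 100, n_scaffolds = 4, sequences = TRUE)
  g <- simulateAncestralGenome(cfg, seed = 3)
  expect_equal(nrow(g), 100L)
  for (sc in unique(g$scaffold))
    expect_equal(sort(g$rank[g$scaffold == sc]),
                 seq_len(sum(g$scaffold == sc)) - 1L)
  expect_true(all(nchar(g$cds) %% 3 == 0))
  for (x in g$cds[1:10]) {
    cod <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
    expect_false(any(cod %in% c("TAA", "TAG", "TGA")))
  }
  big <- simulateAncestralGenome(simConfig(n_genes = 5000), seed = 4)
  m <- mean(log(big$fpkm))
  se <- sd(log(big$fpkm)) / sqrt(5000)
  expect_lt(abs(m - 2), 3 * se)
})

test_that("WGD doubles every gene preserving mirror order", {
  g <- simulateAncestralGenome(simConfig(n_genes = 100, n_scaffolds = 4,
                                         sequences = FALSE), seed = 5)
  w <- applyWGD(g)
  expect_equal(nrow(w$genome), 200L)
  expect_equal(nrow(w$anchors), 100L)
  for (sc in unique(g$scaffold)) {
    oa <- w$genome$pair_id[w$genome$scaffold == paste0(sc, "a")]
    ob <- w$genome$pair_id[w$genome$scaffold == paste0(sc, "b")]
    expect_identical(oa, ob)
  }
})

test_that("zero hazard retains everything; closed-form loss on one branch", {
  sim0 <- simulatePostWGD(fastCfg(base_loss_rate = 0), seed = 6)
  expect_true(all(presenceFromTruth(sim0) == "BOTH"))

  cfg <- simConfig(n_genes = 5000, n_scaffolds = 10, n_ingroup = 2,
                   n_outgroup = 0, depth = 1, wgd_stem = 0,
                   base_loss_rate = 0.5, expr_beta = 0, sequences = FALSE,
                   sgd_rate = 0, conversion_rate = 0,
                   translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 7)
  p <- exp(-0.5 * 1)
  ret <- mean(presenceFromTruth(sim)[, 1] == "BOTH")
  expect_lt(abs(ret - p), 2.58 * sqrt(p * (1 - p) / 5000))
})

test_that("truth replay reproduces leaf states exactly", {
  cfg <- simConfig(n_genes = 300, n_scaffolds = 4, n_ingroup = 5,
                   n_outgroup = 1, depth = 1, wgd_stem = 0.1,
                   base_loss_rate = 0.8, sequences = FALSE,
                   sgd_rate = 2, translocation_rate = 0.01,
                   conversion_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 8)
  expect_identical(replayTruth(sim), presenceFromTruth(sim))
})

test_that("dataset write/read round-trips sequences and identifiers", {
  cfg <- simConfig(n_genes = 40, n_scaffolds = 2, n_ingroup = 2,
                   n_outgroup = 1, depth = 0.3, wgd_stem = 0.05,
                   base_loss_rate = 0.5, sequences = TRUE, sgd_rate = 0,
                   conversion_rate = 0, translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 9)
  dir <- tempfile("dataset")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  writeDataset(sim, dir)
  back <- readDataset(dir)
  for (sp in names(leafGenomes(sim))) {
    g0 <- leafGenomes(sim)[[sp]]
    g1 <- back$genomes[[sp]]
    expect_identical(g1$cds[match(g0$gene_id, g1$gene_id)], g0$cds)
    # every expressed gene exists in the position table
    ex <- read.table(file.path(dir, paste0(sp, ".expr.tsv")),
                     header = TRUE, sep = "\t")
    expect_true(all(ex$gene_id %in% g1$gene_id))
  }
  expect_identical(ape::write.tree(back$tree),
                   ape::write.tree(speciesTree(sim)))
})

test_that("planted duplications sit at their requested divergence", {
  cfg <- simConfig(n_genes = 60, n_scaffolds = 2, n_ingroup = 2,
                   n_outgroup = 0, depth = 0.2, wgd_stem = 0,
                   base_loss_rate = 0, sequences = TRUE, sgd_rate = 0,
                   conversion_rate = 0, translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 10)
  g <- leafGenomes(sim)[["aur01"]]
  pl <- plantSGDs(g, n = 20, age = 0.3, seed = 11)
  cds <- setNames(pl$genome$cds, pl$genome$gene_id)
  ks <- vapply(seq_len(20), function(i)
    estimateKsKa(cds[[pl$pairs$gene1[i]]], cds[[pl$pairs$gene2[i]]],
                 aligned = TRUE)$ks, numeric(1))
  expect_lt(abs(mean(ks) - 0.3), 0.05)
  # ranks still contiguous after insertion
  out <- pl$genome
  for (sc in unique(out$scaffold))
    expect_equal(sort(out$rank[out$scaffold == sc]),
                 seq_len(sum(out$scaffold == sc)) - 1L)
})
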