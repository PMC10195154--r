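# Anchor detection, block merging, paralogon fusion, locus status and
# ancestral reconstruction.

mkAnchors <- function(r1, r2, s1 = "sA", s2 = "sB") {
  data.frame(gene1 = sprintf("x%02d", seq_along(r1)),
             gene2 = sprintf("y%02d", seq_along(r1)),
             scaffold1 = s1, rank1 = r1, scaffold2 = s2, rank2 = r2,
             stringsAsFactors = FALSE)
}

test_that("anchors on a freshly doubled genome are one per ancestral gene", {
  g <- simulateAncestralGenome(
    simConfig(n_genes = 30, n_scaffolds = 2, sequences = TRUE), seed = 41)
  w <- applyWGD(g)
  genome <- data.frame(gene_id = w$genome$id, species = "sp",
                       scaffold = w$genome$scaffold, rank = w$genome$rank,
                       stringsAsFactors = FALSE)
  prot <- setNames(translateCDS(w$genome$cds), w$genome$id)
  anch <- findAnchors(genome, allVsAllHits(prot))
  expect_equal(nrow(anch), 30L)
  expect_true(all(anch$gene1 < anch$gene2))
  # genome without duplicates: no anchors
  prot1 <- setNames(translateCDS(g$cds), g$id)
  expect_equal(nrow(findAnchors(
    data.frame(gene_id = g$id, scaffold = g$scaffold, rank = g$rank),
    allVsAllHits(prot1))), 0L)
})

test_that("block merging chains colinear anchors and splits at gaps", {
  one <- mergeBlocks(mkAnchors(0:9, 0:9), min_anchors = 3, max_gap = 5)
  expect_equal(nrow(one$blocks), 1L)
  expect_equal(one$blocks$n_anchors, 10L)

  two <- mergeBlocks(mkAnchors(c(0:4, 16:20), c(0:4, 16:20)),
                     min_anchors = 3, max_gap = 5)
  expect_equal(nrow(two$blocks), 2L)

  # short chains are discarded
  few <- mergeBlocks(mkAnchors(0:1, 0:1), min_anchors = 3, max_gap = 5)
  expect_equal(nrow(few$blocks), 0L)

  # a self-overlapping chain (tandem array) is never a block
  tandem <- mergeBlocks(mkAnchors(c(0, 2, 4), c(1, 3, 5), "sA", "sA"),
                        min_anchors = 3, max_gap = 5)
  expect_equal(nrow(tandem$blocks), 0L)
})

test_that("paralogon fusion joins co-oriented adjacent blocks", {
  b1 <- mergeBlocks(mkAnchors(c(0:4, 10:14), c(0:4, 10:14)),
                    min_anchors = 3, max_gap = 4)
  expect_equal(nrow(b1$blocks), 2L)
  fused <- fuseParalogons(b1$blocks, max_block_gap = 10)
  expect_equal(length(unique(fused$paralogon_id)), 1L)
  far <- fuseParalogons(b1$blocks, max_block_gap = 2)
  expect_equal(length(unique(far$paralogon_id)), 2L)
})

test_that("paralogon detection recovers simulator truth", {
  cfg <- simConfig(n_genes = 300, n_scaffolds = 3, n_ingroup = 2,
                   n_outgroup = 0, depth = 0.5, wgd_stem = 0.1,
                   base_loss_rate = 0.6, expr_beta = 0, sequences = TRUE,
                   sgd_rate = 0, conversion_rate = 0,
                   translocation_rate = 0.01)
  sim <- simulatePostWGD(cfg, seed = 42)
  g <- leafGenomes(sim)[["aur01"]]
  hits <- allVsAllHits(setNames(translateCDS(g$cds), g$gene_id))
  pset <- detectParalogons(g, hits)
  loci <- paralogonLoci(pset)
  lg <- data.frame(gene = c(loci$gene1, loci$gene2),
                   par = rep(loci$paralogon_id, 2))
  lg <- lg[!is.na(lg$gene), ]
  lg$anc <- g$anc_scaffold[match(lg$gene, g$gene_id)]
  maj <- tapply(lg$anc, lg$par,
                function(x) names(sort(table(x), decreasing = TRUE))[1])
  expect_gte(mean(lg$anc == maj[lg$par]), 0.95)
  expect_gte(nrow(lg) / nrow(g), 0.9)

  anc1 <- reconstructAncestor(pset, g, seed = 1)
  anc2 <- reconstructAncestor(pset, g, seed = 1)
  expect_identical(anc1, anc2)
  expect_equal(nrow(anc1), 300L)
  # every surviving gene represented at most once
  expect_false(anyDuplicated(anc1$gene_id) > 0)
})

test_that("all-single-copy loci reconstruct to the survivor sequence", {
  loci <- data.frame(locus_id = c("L1", "L2"), paralogon_id = "P1",
                     block_id = "B1", ord = 1:2, status = "SINGLE_COPY",
                     gene1 = c("g1", "g2"), gene2 = NA,
                     stringsAsFactors = FALSE)
  pset <- new("ParalogonSet", species = "sp",
              anchors = data.frame(gene1 = character(0),
                                   gene2 = character(0),
                                   block_id = character(0)),
              blocks = data.frame(), loci = loci)
  genome <- data.frame(gene_id = c("g1", "g2"))
  anc <- reconstructAncestor(pset, genome, seed = 1,
                             include_unassigned = FALSE)
  expect_identical(anc$gene_id, c("g1", "g2"))
})
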