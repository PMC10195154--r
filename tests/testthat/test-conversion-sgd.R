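# Ks profiles, changepoint detection, conversion flagging and
# single-gene-duplication calling.

test_that("Ks profiles follow ancestral order and skip empty paralogons", {
  loci <- data.frame(locus_id = sprintf("L%d", 1:6), paralogon_id = "P1",
                     block_id = "B1", ord = c(3, 1, 2, 4, 5, 6),
                     status = c(rep("RETAINED_BOTH", 5), "SINGLE_COPY"),
                     gene1 = sprintf("a%d", 1:6),
                     gene2 = c(sprintf("b%d", 1:5), NA),
                     stringsAsFactors = FALSE)
  pset <- new("ParalogonSet", species = "sp", anchors = data.frame(),
              blocks = data.frame(), loci = loci)
  ks <- data.frame(gene1 = sprintf("a%d", 1:5),
                   gene2 = sprintf("b%d", 1:5), ks = (1:5) / 10)
  pr <- ksProfile(pset, ks)
  expect_equal(nrow(pr), 5L)
  expect_equal(pr$gene1, c("a2", "a3", "a1", "a4", "a5"))
  empty <- loci; empty$status <- "SINGLE_COPY"
  pset2 <- new("ParalogonSet", species = "sp", anchors = data.frame(),
               blocks = data.frame(), loci = empty)
  expect_equal(nrow(ksProfile(pset2, ks)), 0L)
})

test_that("changepoints match the exhaustive single-split oracle", {
  expect_equal(nrow(detectChangepoints(rep(1, 20))), 0L)
  set.seed(71)
  x <- c(rnorm(10, 1, 0.05), rnorm(10, 0.2, 0.05))
  cp <- detectChangepoints(x)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$index, singleSplitOracle(x))
  expect_equal(cp$index, 10L)
  expect_equal(cp$direction, "down")
  # reversal symmetry up to index mirroring
  cpr <- detectChangepoints(rev(x))
  expect_equal(cpr$index, length(x) - cp$index)
})

test_that("downward segments are flagged as conversion, upward are not", {
  set.seed(72)
  x <- c(rnorm(10, 1, 0.05), rnorm(10, 0.2, 0.05))
  fl <- flagConvertedSegments(x, detectChangepoints(x))
  expect_true(fl$flagged[fl$start == 11])
  expect_false(fl$flagged[fl$start == 1])
  up <- c(rnorm(10, 0.5, 0.05), rnorm(10, 1.5, 0.05))
  flu <- flagConvertedSegments(up, detectChangepoints(up))
  expect_false(flu$flagged[flu$start == 11])
})

test_that("conversion tracts in a simulated genome produce Ks valleys", {
  cfg <- simConfig(n_genes = 120, n_scaffolds = 1, n_ingroup = 2,
                   n_outgroup = 0, depth = 0.6, wgd_stem = 0.1,
                   base_loss_rate = 0, sequences = TRUE, sgd_rate = 0,
                   conversion_rate = 3, conversion_tract_len = 10,
                   translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 73)
  g <- leafGenomes(sim)[["aur01"]]
  key <- paste0(g$pair_id, g$copy)
  tracts <- groundTruth(sim)$tracts
  tr <- speciesTree(sim)
  onpath <- tracts$node %in% c(attr(tr, "wgd_node"),
                               ape::nodepath(tr, 3, 1))
  expect_gt(sum(onpath), 0)
  converted <- unique(tracts$pair_id[onpath])
  ks <- vapply(unique(g$pair_id), function(p) {
    a <- g$cds[match(paste0(p, "A"), key)]
    b <- g$cds[match(paste0(p, "B"), key)]
    estimateKsKa(a, b, aligned = TRUE)$ks
  }, numeric(1))
  # converted pairs look younger than unconverted ones
  expect_lt(mean(ks[names(ks) %in% converted]),
            mean(ks[!(names(ks) %in% converted)]))
})

test_that("SGD filters drop anchors, out-of-block pairs and old pairs", {
  cfg <- simConfig(n_genes = 200, n_scaffolds = 2, n_ingroup = 2,
                   n_outgroup = 0, depth = 0.4, wgd_stem = 0.1,
                   base_loss_rate = 0.4, sequences = TRUE, sgd_rate = 0,
                   conversion_rate = 0, translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 74)
  g <- leafGenomes(sim)[["aur01"]]
  hits <- allVsAllHits(setNames(translateCDS(g$cds), g$gene_id))
  pset <- detectParalogons(g, hits)
  none <- findSingleGeneDuplications(g, hits, pset)
  expect_equal(nrow(none), 0L)   # without SGD events every RBH is WGD-derived

  old <- plantSGDs(g, n = 8, age = 1.3, seed = 75)
  hits2 <- allVsAllHits(setNames(translateCDS(old$genome$cds),
                                 old$genome$gene_id))
  pset2 <- detectParalogons(old$genome, hits2)
  sgd2 <- findSingleGeneDuplications(old$genome, hits2, pset2)
  planted <- paste(pmin(old$pairs$gene1, old$pairs$gene2),
                   pmax(old$pairs$gene1, old$pairs$gene2))
  expect_false(any(paste(sgd2$gene1, sgd2$gene2) %in% planted))
  filt <- attr(sgd2, "filters")
  expect_true(all(c("rbh_pairs", "non_anchor", "in_block", "ks_pass")
                  %in% names(filt)))
})
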