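# Alignment scoring, RBH, family clustering, Ks/Ka and gene trees.

test_that("alignment score matches a quadratic-time affine-gap oracle", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    a <- paste(sample(aas, sample(8:30, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:30, 1), TRUE), collapse = "")
    sp <- scorePair(a, b)
    expect_equal(sp$score, nwOracle(a, b), tolerance = 1e-9)
    expect_equal(sp$score, scorePair(b, a)$score, tolerance = 1e-9)
  }
  expect_equal(scorePair("MKVLA", "MKVLA")$identity, 1.0)
  expect_error(scorePair("MKV!", "MKV"), "amino-acid")
})

test_that("reciprocal best hits follow the mutual-best definition", {
  one <- allVsAllHits(c(x = "MKVLAWMKVLAW"), c(y = "MKVLAWMKVLAW"))
  expect_equal(nrow(reciprocalBestHits(one)), 1L)
  # a's best is b, but b's best is c: no pair
  hits <- data.frame(query = c("a", "b", "b", "c"),
                     subject = c("b", "a", "c", "b"),
                     score = c(10, 5, 9, 9))
  rbh <- reciprocalBestHits(hits)
  expect_false(any(rbh$gene1 == "a"))
  expect_true(any(rbh$gene1 == "b" & rbh$gene2 == "c"))
})

test_that("family clustering joins RBH components deterministically", {
  hits <- data.frame(query = c("a1", "b1", "a2", "b2"),
                     subject = c("b1", "a1", "b2", "a2"),
                     score = c(9, 9, 8, 8))
  fam <- clusterFamilies(hits)
  expect_equal(length(unique(fam$family_id)), 2L)
  # permutation invariance
  fam2 <- clusterFamilies(hits[c(3, 1, 4, 2), ])
  expect_identical(fam, fam2)

  # no-evolution doubled genome: one family per ancestral gene
  g <- simulateAncestralGenome(
    simConfig(n_genes = 40, n_scaffolds = 2, sequences = TRUE), seed = 32)
  w <- applyWGD(g)
  prot <- setNames(translateCDS(w$genome$cds), w$genome$id)
  fam <- clusterFamilies(allVsAllHits(prot))
  expect_equal(length(unique(fam$family_id)), 40L)
})

test_that("Ks/Ka counting matches the hand-enumerated codon oracle", {
  same <- estimateKsKa("ATGGCTAAA", "ATGGCTAAA", aligned = TRUE)
  expect_equal(same$ks, 0)
  expect_equal(same$ka, 0)

  # ten proline codons, one synonymous third-position change:
  # S = 10 sites (third position fully degenerate, others zero),
  # ps = 1/10, Ks = -3/4 log(1 - 4 ps / 3), Ka = 0
  a <- paste(rep("CCT", 10), collapse = "")
  b <- paste(c(rep("CCT", 9), "CCA"), collapse = "")
  est <- estimateKsKa(a, b, aligned = TRUE)
  expect_equal(est$ka, 0)
  expect_equal(est$ks, -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  # symmetry
  est2 <- estimateKsKa(b, a, aligned = TRUE)
  expect_equal(est$ks, est2$ks)

  # saturation flag
  sat <- estimateKsKa(paste(rep("CCT", 20), collapse = ""),
                      paste(rep(c("CCA", "CCG", "CCC", "CCT"), 5),
                            collapse = ""), aligned = TRUE)
  expect_true(sat$saturated)
})

test_that("Ks estimates recover the generative divergence at Ks 0.3", {
  tab <- paralogon:::.codonTables()
  set.seed(33)
  ks <- numeric(300)
  for (i in seq_along(ks)) {
    a0 <- paste(sample(tab$sense, 150, TRUE), collapse = "")
    a <- paralogon:::.mutateCDS1(a0, 0.15, 0.05 * 0.15, tab)
    b <- paralogon:::.mutateCDS1(a0, 0.15, 0.05 * 0.15, tab)
    ks[i] <- estimateKsKa(a, b, aligned = TRUE)$ks
  }
  expect_lt(abs(mean(ks) / 0.3 - 1), 0.1)
})

test_that("NJ recovers additive topologies and handles tiny families", {
  tr2 <- buildGeneTree(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(ape::Ntip(tr2), 2L)
  tr3 <- buildGeneTree(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(ape::Ntip(tr3), 3L)

  # additive distances from a known 5-leaf tree are recovered exactly
  ref <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:0.5):2,e:3);")
  D <- ape::cophenetic.phylo(ref)
  nj5 <- buildGeneTree(D)
  expect_equal(unname(c(ape::dist.topo(ape::unroot(nj5),
                                       ape::unroot(ref)))), 0)
})
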