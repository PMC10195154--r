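# Ortholog candidates, scaffold scoring, 1-to-2 resolution, gene-tree
# groups and paralogon chains.

test_that("scaffold scores count candidate pairs and conserve totals", {
  cand <- data.frame(family_id = sprintf("F%d", 1:5),
                     gene_a = sprintf("a%d", 1:5),
                     gene_b = sprintf("b%d", 1:5),
                     scaffold_a = c("s1", "s1", "s1", "s2", "s2"),
                     scaffold_b = c("t1", "t1", "t1", "t2", "t9"),
                     type = "1to1", best = TRUE, score = 1)
  sc <- scoreScaffolds(cand)
  expect_equal(sc$score[sc$scaffold_a == "s1" & sc$scaffold_b == "t1"], 3L)
  expect_equal(sum(sc$score), nrow(cand))
  expect_false(any(paste(sc$scaffold_a, sc$scaffold_b) == "s1 t2"))
})

test_that("1-to-2 resolution follows the higher scaffold score, ties stay open", {
  cand <- data.frame(family_id = "F1", gene_a = "a1",
                     gene_b = c("b1", "b2"),
                     scaffold_a = "s1", scaffold_b = c("t1", "t2"),
                     type = "1to2", best = c(TRUE, FALSE),
                     score = c(100, 90))
  hi <- data.frame(scaffold_a = c("s1", "s1"),
                   scaffold_b = c("t1", "t2"), score = c(12L, 3L))
  res <- resolveOneToTwo(cand, hi)
  expect_equal(res$gene_b, "b1")
  expect_equal(res$type, "resolved")
  tie <- data.frame(scaffold_a = c("s1", "s1"),
                    scaffold_b = c("t1", "t2"), score = c(5L, 5L))
  res2 <- resolveOneToTwo(cand, tie)
  expect_equal(res2$type, "unresolved")
  # never selects a gene outside the candidate pair
  expect_true(all(res$gene_b %in% cand$gene_b))
})

test_that("gene-tree groups split WGD copies and never repeat a species", {
  sof <- setNames(rep(c("sp1", "sp2", "sp3", "sp4"), 2),
                  c(paste0(c("sp1", "sp2", "sp3", "sp4"), "_A"),
                    paste0(c("sp1", "sp2", "sp3", "sp4"), "_B")))
  nwk <- paste0("(((sp1_A:1,sp2_A:1):1,(sp3_A:1,sp4_A:1):1):2,",
                "((sp1_B:1,sp2_B:1):1,(sp3_B:1,sp4_B:1):1):2);")
  gr <- groupsFromGeneTree(ape::read.tree(text = nwk), sof)
  sizes <- table(gr$group_id)
  expect_equal(sort(as.integer(sizes)), c(4L, 4L))
  for (g in unique(gr$group_id)) {
    mem <- gr$gene_id[gr$group_id == g]
    expect_false(anyDuplicated(sof[mem]) > 0)
    # one WGD copy per group
    expect_equal(length(unique(sub(".*_", "", mem))), 1L)
  }
  tri <- groupsFromGeneTree(
    ape::read.tree(text = "((sp1_A:1,sp2_A:1):1,sp3_A:2);"), sof)
  expect_equal(nrow(tri), 3L)
  expect_equal(length(unique(tri$group_id)), 1L)
})

test_that("greedy chains take heaviest edges first and reuse no node", {
  groups <- data.frame(
    group_id = rep(sprintf("G%02d", 1:20), each = 2),
    gene_id = c(rbind(sprintf("u%02d", 1:20), sprintf("v%02d", 1:20))))
  gp <- c(setNames(rep("sp1:P1", 20), sprintf("u%02d", 1:20)),
          setNames(rep("sp2:P1", 20), sprintf("v%02d", 1:20)))
  ch <- chainParalogons(groups, gp)
  expect_equal(ch$graph$weight, 20L)
  expect_equal(sort(unique(ch$chains$node)), c("sp1:P1", "sp2:P1"))

  # triangle 10/9/1: chain takes 10 then 9; edge 1 is never used
  mk <- function(n, a, b) data.frame(
    group_id = sprintf("%s%s%02d", a, b, seq_len(n)),
    gene_id = c(rbind(sprintf("%s_%s%02d", a, b, seq_len(n)),
                      sprintf("%s_%s%02d", b, a, seq_len(n)))))
  groups2 <- rbind(mk(10, "A", "B"), mk(9, "B", "C"), mk(1, "A", "C"))
  groups2$group_id <- rep(sprintf("G%03d", seq_len(nrow(groups2) / 2)),
                          each = 2)
  gp2 <- setNames(paste0(sub("_.*", "", groups2$gene_id), ":P"),
                  groups2$gene_id)
  ch2 <- chainParalogons(groups2, gp2)
  expect_equal(length(unique(ch2$chains$chain_id)), 1L)
  expect_equal(ch2$chains$node[2], "B:P")   # B is the middle of the path
  # node order invariance via deterministic tie-breaking
  ch3 <- chainParalogons(groups2[nrow(groups2):1, ], gp2)
  expect_identical(sort(ch2$chains$node), sort(ch3$chains$node))
})

test_that("outgroup orthologs take the top total score per family", {
  fam <- data.frame(family_id = c("F1", "F1", "F2"),
                    gene_id = c("i1", "i2", "i3"))
  hits <- data.frame(query = c("o1", "o1", "o2", "o2"),
                     subject = c("i1", "i2", "i1", "i3"),
                     score = c(10, 10, 15, 4))
  oo <- outgroupOrthologs(fam, hits)
  expect_equal(oo$outgroup_gene[oo$family_id == "F1"], "o1")
  expect_equal(oo$outgroup_gene[oo$family_id == "F2"], "o2")
  none <- outgroupOrthologs(fam, hits[0, ])
  expect_equal(nrow(none), 0L)
})
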