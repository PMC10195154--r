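# Ladder-subtree extraction and the duplication-node placement vote.

sof4 <- setNames(rep(c("t1", "t2", "t3", "og"), each = 2),
                 paste0(rep(c("t1", "t2", "t3", "og"), each = 2),
                        c("_x", "_y")))

test_that("subtree extraction requires one copy of every quartet taxon", {
  tr <- ape::read.tree(
    text = "(((t1_x:1,t2_x:1):1,t3_x:2):1,og_x:3);")
  q <- c("t1", "t2", "t3", "og")
  expect_identical(ape::write.tree(extractLadderSubtree(tr, sof4, q)),
                   ape::write.tree(tr))
  miss <- ape::drop.tip(tr, "og_x")
  expect_null(extractLadderSubtree(miss, sof4, q))
  # pruning to the quartet preserves the induced topology
  big <- ape::read.tree(text = paste0(
    "((((t1_x:1,t1_y:1):1,(t2_x:1,t2_y:1):1):1,",
    "(t3_x:2,t3_y:2):1):1,og_x:4);"))
  sub <- extractLadderSubtree(big, sof4, q)
  expect_equal(sort(sub$tip.label), sort(big$tip.label))
})

test_that("placement vote maps duplication spans to ladder branches", {
  q <- c("t1", "t2", "t3", "og")
  # all copies duplicated at the subtree root (og included)
  root_dup <- ape::read.tree(text = paste0(
    "(((t1_x:1,(t2_x:1,t3_x:1):1):1,og_x:2):1,",
    "((t1_y:1,t2_y:1):1,og_y:2):1);"))
  v1 <- votePlacement(list(root_dup), sof4, q)
  expect_equal(v1$percent[v1$branch == "root"], 100)

  # clade-wide duplication, single-copy outgroup
  clade <- ape::read.tree(text = paste0(
    "((((t1_x:1,t2_x:1):1,t3_x:2):1,",
    "((t1_y:1,t2_y:1):1,t3_y:2):1):1,og_x:4);"))
  v2 <- votePlacement(list(clade), sof4, q)
  expect_equal(v2$percent[v2$branch == "clade_base"], 100)

  # no duplicated species anywhere: unassigned
  single <- ape::read.tree(
    text = "(((t1_x:1,t2_x:1):1,t3_x:2):1,og_x:3);")
  v3 <- votePlacement(list(single), sof4, q)
  expect_equal(v3$percent[v3$branch == "unassigned"], 100)

  # percentages always total 100 and input order does not matter
  v4 <- votePlacement(list(clade, root_dup, single), sof4, q)
  v5 <- votePlacement(list(single, clade, root_dup), sof4, q)
  expect_equal(sum(v4$percent), 100)
  expect_identical(v4, v5)
  expect_true(all(v4$band %in% c("orange", "blue", "grey")))
})
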