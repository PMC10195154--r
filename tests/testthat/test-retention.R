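# Expression transform, cross-species retention rates, binned profiles
# and category bias.

test_that("expression level is log10(FPKM + 0.1)", {
  expect_equal(expressionLevel(c(0, 0.9, 99.9)), c(-1, 0, 2))
  expect_error(expressionLevel(-1))
})

test_that("cross-species retention follows the both/with-ortholog ratio", {
  st <- matrix(NA_character_, 3, 12,
               dimnames = list(c("g1", "g2", "g3"), sprintf("s%02d", 1:12)))
  st["g1", ] <- c(rep("BOTH", 10), "ONE", "ONE")
  st["g2", ] <- rep("ONE", 12)
  # g3 has no ortholog anywhere: excluded, not zero
  rr <- crossSpeciesRetention(st)
  expect_equal(rr$rate[rr$gene_id == "g1"], 10 / 12)
  expect_equal(rr$rate[rr$gene_id == "g2"], 0)
  expect_false("g3" %in% rr$gene_id)
})

test_that("quantile bins have equal counts and reconstruct the global mean", {
  set.seed(61)
  expr <- rnorm(140)
  rate <- runif(140)
  br <- binnedRetention(expr, rate, 14)
  expect_equal(br$n, rep(10L, 14))
  expect_equal(sum(br$mean_rate * br$n) / sum(br$n), mean(rate))
  flat <- binnedRetention(expr, rep(0.4, 140), 14)
  expect_true(all(abs(flat$mean_rate - 0.4) < 1e-12))
  expect_true(all(flat$ci_hi - flat$ci_lo < 1e-12))
})

test_that("category bias finds planted retention odds and stays null-calibrated", {
  set.seed(62)
  n <- 3000
  cats <- sample(sprintf("C%d", 1:6), n, TRUE)
  expr <- rnorm(n)
  base <- plogis(0.8 * expr)          # expression-linked retention
  pr <- ifelse(cats == "C3", plogis(qlogis(base) + log(3)), base)
  rate_a <- rbinom(n, 5, pr) / 5
  rate_b <- rbinom(n, 5, pr) / 5
  cb <- categoryBias(cats, rate_a, rate_b, expr, n_perm = 299)
  expect_gt(cb$cross_clade_r, 0.8)
  expect_lt(cb$table$q[cb$table$category == "C3"], 0.05)

  # shuffled labels: enrichment p-values roughly uniform
  cb0 <- categoryBias(sample(cats), rate_a, rate_b, expr, n_perm = 299)
  ks <- suppressWarnings(stats::ks.test(cb0$table$p, "punif"))
  expect_gt(ks$p.value, 0.05)
  # identical clade rates give r = 1
  cb1 <- categoryBias(cats, rate_a, rate_a, expr, n_perm = 99)
  expect_equal(cb1$cross_clade_r, 1)
})
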