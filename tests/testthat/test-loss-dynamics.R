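# Parsimony reconstruction with missing-data rules, survival and decay,
# loss-pattern classification and expression-biased loss.

test_that("child-state combination follows the no-gain rule table", {
  cherry <- ape::read.tree(text = "(x:1,y:1);")
  st <- function(a, b) {
    m <- matrix(c(a, b), 1, 2, dimnames = list("p1", c("x", "y")))
    anc <- ancestralStates(cherry, m)
    anc$states[3, 1]
  }
  expect_identical(st("BOTH", "ONE"), "BOTH")
  expect_identical(st("ONE", "ONE"), "ONE")
  expect_identical(st(NA, "BOTH"), "BOTH")
  expect_identical(st(NA, "ONE"), NA_character_)
  expect_identical(st(NA, NA), NA_character_)
})

test_that("loss events sit on branches from BOTH parents to ONE children", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  m <- presenceMat(a = c("BOTH", "ONE"), b = c("BOTH", "ONE"),
                   c = c("ONE", "BOTH"), d = c("BOTH", "BOTH"))
  anc <- ancestralStates(tr, m)
  # row 1: c alone lost -> one event on c's terminal branch
  e1 <- anc$events[anc$events$pair_id == "p01", ]
  expect_equal(e1$branch_label, "c")
  # row 2: a and b lost -> single event on their stem (Dollo minimum)
  e2 <- anc$events[anc$events$pair_id == "p02", ]
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$node, ape::getMRCA(tr, c("a", "b")))
})

test_that("survival is 1 at the root and non-increasing toward the tips", {
  cfg <- simConfig(n_genes = 800, n_scaffolds = 4, n_ingroup = 6,
                   n_outgroup = 0, depth = 1, wgd_stem = 0,
                   base_loss_rate = 0.6, sequences = FALSE, sgd_rate = 0,
                   conversion_rate = 0, translocation_rate = 0)
  sim <- simulatePostWGD(cfg, seed = 51)
  tr <- wgdSubtree(speciesTree(sim))
  sv <- survivalCurve(ancestralStates(tr, presenceFromTruth(sim)), tr)
  root <- ape::Ntip(tr) + 1L
  expect_equal(sv$survival[root], 1)
  for (tip in seq_len(ape::Ntip(tr))) {
    path <- ape::nodepath(tr, root, tip)
    expect_true(all(diff(sv$survival[path]) <= 1e-12))
  }
})

test_that("decay fitting is exact on noiseless data and detects two phases", {
  d <- seq(0, 3, length.out = 25)
  f1 <- fitDecay(d, exp(-0.5 * d))
  expect_equal(f1$lambda, 0.5, tolerance = 1e-9)
  expect_equal(f1$model, "one_phase")

  set.seed(52)
  s2 <- pmax(0.5 * exp(-2 * d) + 0.5 * exp(-0.1 * d) +
               rnorm(25, 0, 0.005), 1e-4)
  f2 <- fitDecay(d, s2)
  expect_equal(f2$model, "two_phase")

  # binomially sampled one-phase points rarely prefer two phases
  pref <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    s <- rbinom(25, 2000, exp(-0.5 * d)) / 2000
    fitDecay(d, s)$model
  }, character(1))
  expect_gte(mean(pref == "one_phase"), 0.9)
})

test_that("independent-contrast correlation matches a first-principles oracle", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:2,d:2):1);")
  set.seed(53)
  x <- setNames(rnorm(4), c("a", "b", "c", "d"))
  y <- setNames(rnorm(4), c("a", "b", "c", "d"))
  rv <- retentionVsDivergence(y, x, tr)
  cx <- picOracle(tr, x); cy <- picOracle(tr, y)
  r_oracle <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(rv$r[rv$method == "pic"], r_oracle, tolerance = 1e-9)
  # perfectly anticorrelated vectors
  rv2 <- retentionVsDivergence(setNames(4:1, letters[1:4]),
                               setNames(1:4, letters[1:4]), tr)
  expect_equal(rv2$r[rv2$method == "pearson"], -1)
})

test_that("loss patterns classify parallel, reciprocal and shared losses", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  attr(tr, "wgd_node") <- 5L
  ev <- data.frame(
    pair_id = c("p1", "p1", "p2", "p2", "p3"),
    node = c(1L, 3L, 1L, 3L, 6L),
    lost_copy = c("A", "A", "A", "B", "A"))
  cl <- classifyLossPattern(tr, ev, "a", "c")
  expect_equal(cl$pattern[cl$pair_id == "p1"], "parallel")
  expect_equal(cl$pattern[cl$pair_id == "p2"], "reciprocal")
  cl2 <- classifyLossPattern(tr, ev, "a", "b")
  expect_equal(cl2$pattern[cl2$pair_id == "p3"], "none")
  # counts symmetric in species order
  cnt <- lossPatternCounts(tr, ev)
  expect_true(all(cnt$n_parallel >= 0 & cnt$n_reciprocal >= 0))
  expect_equal(nrow(cnt), 6L)
})

test_that("degenerate parallel-fraction inputs report NA", {
  cnt <- data.frame(species1 = "a", species2 = c("b", "c", "d"),
                    n_parallel = c(5L, 5L, 5L), n_reciprocal = c(5L, 5L, 5L),
                    distance = c(1, 2, 3))
  expect_true(is.na(parallelTrend(cnt)$r))
})

test_that("extreme expression-biased loss is detected with high confidence", {
  pairs <- data.frame(expr_div = runif(200),
                      lost_in_b = c(rep(TRUE, 50), rep(FALSE, 150)),
                      lost_low = c(rep(TRUE, 50), rep(NA, 150)))
  eb <- expressionBiasedLoss(pairs)
  expect_equal(eb$frac_low, 1)
  expect_lt(eb$prop_p, 0.001)
})
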