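# Mapping copy losses onto the species tree by parsimony (gain
# probability zero, explicit NA rules), survival-decay fitting, and
# parallel/reciprocal and expression-biased loss statistics.

#' Ingroup (post-WGD) subtree of a simulation tree
#'
#' @param tree species tree carrying a \code{wgd_node} attribute.
#' @return the rooted subtree descending from the WGD node.
#' @export
wgdSubtree <- function(tree) {
  wgd <- attr(tree, "wgd_node")
  .assert(!is.null(wgd), "tree lacks a wgd_node attribute")
  if (wgd == ape::Ntip(tree) + 1L) return(tree)
  ape::extract.clade(tree, wgd)
}

#' Ancestral duplicate states by parsimony
#'
#' Post-order reconstruction of per-pair states over a rooted binary
#' tree, assuming the probability of duplicate gain is zero. The child
#' combination rules are: any child BOTH makes the ancestor BOTH;
#' (ONE, ONE) gives ONE; missing data propagate as
#' (NA, BOTH) -> BOTH, (NA, ONE) -> NA, (NA, NA) -> NA. A loss event is
#' assigned to every branch whose parent is BOTH and whose child is ONE.
#'
#' @param tree rooted binary \code{ape::phylo}; tip labels must all be
#'   columns of \code{presence}.
#' @param presence character matrix, rows = ancestral pairs, columns =
#'   species, cells in \{"BOTH", "ONE", NA\}.
#' @return list: \code{states} (character matrix, (tips+nodes) x pairs),
#'   \code{events} (data.frame \code{pair_id, node, branch_label}),
#'   \code{n_both} (per-node BOTH counts).
#' @export
ancestralStates <- function(tree, presence) {
  ntip <- ape::Ntip(tree)
  .assert(all(tree$tip.label %in% colnames(presence)),
          "presence matrix lacks some tree leaves")
  presence[presence == "NA"] <- NA_character_
  np <- nrow(presence)
  states <- matrix(NA_character_, ntip + tree$Nnode, np)
  for (i in seq_len(ntip))
    states[i, ] <- presence[, tree$tip.label[i]]
  comb <- function(a, b) {
    out <- rep(NA_character_, length(a))
    out[a %in% "ONE" & b %in% "ONE"] <- "ONE"
    out[a %in% "BOTH" | b %in% "BOTH"] <- "BOTH"
    out
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  done <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
  for (node in unique(po[, 1])) {
    ch <- po[po[, 1] == node, 2]
    s <- states[ch[1], ]
    for (k in ch[-1]) s <- comb(s, states[k, ])
    states[node, ] <- s
    done[node] <- TRUE
  }
  ev <- list()
  labs <- c(tree$tip.label, sprintf("node%d", ntip + seq_len(tree$Nnode)))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
    hit <- which(states[p, ] %in% "BOTH" & states[c2, ] %in% "ONE")
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.frame(
        pair_id = rownames(presence)[hit], node = c2,
        branch_label = labs[c2], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pair_id = character(0), node = integer(0),
               branch_label = character(0))
  list(states = states, events = events,
       n_both = rowSums(states == "BOTH", na.rm = TRUE))
}

#' Survival curve over tree nodes
#'
#' Survival at a node is the number of pairs reconstructed BOTH at that
#' node divided by the number BOTH at the root; the node's time axis is
#' its distance from the root in branch-length (Ks) units.
#'
#' @param anc result of \code{\link{ancestralStates}}.
#' @param tree the tree used for the reconstruction.
#' @return data.frame \code{node, label, distance, n_both, survival}.
#' @export
survivalCurve <- function(anc, tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  .assert(anc$n_both[root] > 0, "no duplicate pairs at the root")
  d <- ape::node.depth.edgelength(tree)
  labs <- c(tree$tip.label, sprintf("node%d", ntip + seq_len(tree$Nnode)))
  data.frame(node = seq_along(anc$n_both), label = labs, distance = d,
             n_both = anc$n_both,
             survival = anc$n_both / anc$n_both[root])
}

#' Fit exponential decay models to survival points
#'
#' Least-squares fits of the one-phase model S = exp(-lambda d) and the
#' two-phase mixture S = p exp(-l1 d) + (1-p) exp(-l2 d), compared by
#' small-sample AIC (AICc) with a delta > 2 threshold for preferring the
#' two-phase model.
#'
#' @param distance,survival numeric vectors (>= 3 points).
#' @return list: \code{model} ("one_phase"/"two_phase"), \code{lambda}
#'   (one-phase rate), \code{two_phase} (p, l1, l2 or NULL),
#'   \code{delta_aicc} (AICc one-phase minus two-phase), \code{rss}.
#' @export
fitDecay <- function(distance, survival) {
  ok <- is.finite(distance) & is.finite(survival) & survival > 0
  d <- distance[ok]; s <- survival[ok]
  .assert(length(d) >= 3, "need at least 3 survival points")
  l0 <- if (sum(d^2) > 0) max(sum(-d * log(s)) / sum(d^2), 1e-8) else 1e-8
  f1 <- tryCatch(nls(s ~ exp(-l * d), start = list(l = l0)),
                 error = function(e) NULL)
  lam <- if (is.null(f1)) l0 else coef(f1)[["l"]]
  rss1 <- sum((s - exp(-lam * d))^2)
  n <- length(d)
  if (rss1 < 1e-20)
    return(list(model = "one_phase", lambda = lam, two_phase = NULL,
                delta_aicc = NA_real_, rss = rss1))
  aicc <- function(rss, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  f2 <- tryCatch(minpack.lm::nlsLM(
    s ~ p * exp(-l1 * d) + (1 - p) * exp(-l2 * d),
    start = list(p = 0.5, l1 = 3 * lam, l2 = lam / 3),
    lower = c(0, 1e-9, 1e-9), upper = c(1, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  rss2 <- if (is.null(f2)) Inf else sum(residuals(f2)^2)
  delta <- aicc(rss1, 2) - aicc(rss2, 4)
  two <- !is.null(f2) && is.finite(delta) && delta > 2
  list(model = if (two) "two_phase" else "one_phase", lambda = unname(lam),
       two_phase = if (!is.null(f2)) as.list(coef(f2)) else NULL,
       delta_aicc = delta, rss = rss1)
}

#' Retention vs divergence correlation, with and without phylogeny
#'
#' Pearson correlation between per-species ohnolog retention fractions
#' and per-species mean ohnolog Ks, plus the same correlation computed on
#' Felsenstein's phylogenetically independent contrasts (through the
#' origin).
#'
#' @param retention,divergence named numeric vectors (names = species).
#' @param tree species tree containing those tips.
#' @return data.frame with rows \code{pearson} and \code{pic}: r, p, n.
#' @export
retentionVsDivergence <- function(retention, divergence, tree) {
  sp <- intersect(names(retention), tree$tip.label)
  .assert(length(sp) >= 4, "need at least 4 species")
  tr <- ape::keep.tip(tree, sp)
  x <- divergence[sp]; y <- retention[sp]
  ct <- cor.test(x, y)
  px <- ape::pic(x[tr$tip.label], tr)
  py <- ape::pic(y[tr$tip.label], tr)
  r_pic <- sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  fit <- suppressWarnings(summary(lm(py ~ px + 0)))
  p_pic <- if (nrow(fit$coefficients)) fit$coefficients[1, 4] else NA_real_
  data.frame(method = c("pearson", "pic"),
             r = c(unname(ct$estimate), r_pic),
             p = c(ct$p.value, p_pic),
             n = c(length(sp), length(px)))
}

# loss events on the root-to-tip path of one species
#' @noRd
.pathEvents <- function(tree, events, sp) {
  root <- ape::Ntip(tree) + 1L
  tip <- match(sp, tree$tip.label)
  .assert(!is.na(tip), paste("species not in tree:", sp))
  path <- ape::nodepath(tree, root, tip)[-1]
  events[events$node %in% path, , drop = FALSE]
}

#' Classify loss patterns for one species pair
#'
#' For every ohnolog pair lost (independently) in both species: losing
#' the same copy on disjoint branches is a parallel loss, different
#' copies a reciprocal loss; a loss on a shared ancestral branch is a
#' single event and is excluded.
#'
#' @param tree rooted tree whose root is the WGD.
#' @param events loss-event table (\code{pair_id, node, lost_copy});
#'   \code{\link{ancestralStates}} events joined with copy identity, or
#'   simulator truth events.
#' @param species_x,species_y the two species.
#' @return data.frame \code{pair_id, pattern} with pattern in
#'   \{parallel, reciprocal, none\}.
#' @export
classifyLossPattern <- function(tree, events, species_x, species_y) {
  ex <- .pathEvents(tree, events, species_x)
  ey <- .pathEvents(tree, events, species_y)
  shared <- intersect(ex$pair_id, ey$pair_id)
  if (!length(shared))
    return(data.frame(pair_id = character(0), pattern = character(0)))
  ix <- match(shared, ex$pair_id); iy <- match(shared, ey$pair_id)
  same_event <- ex$node[ix] == ey$node[iy]
  pattern <- ifelse(same_event, "none",
                    ifelse(ex$lost_copy[ix] == ey$lost_copy[iy],
                           "parallel", "reciprocal"))
  data.frame(pair_id = shared, pattern = pattern, stringsAsFactors = FALSE)
}

#' Parallel/reciprocal counts for all species pairs
#'
#' @param tree rooted tree whose root is the WGD.
#' @param events loss-event table with copy identity.
#' @return data.frame \code{species1, species2, n_parallel, n_reciprocal,
#'   distance} where distance is from the WGD (root) to the pair's MRCA.
#' @export
lossPatternCounts <- function(tree, events) {
  tips <- sort(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)
  rows <- list()
  for (i in seq_len(length(tips) - 1)) for (j in (i + 1):length(tips)) {
    cl <- classifyLossPattern(tree, events, tips[i], tips[j])
    mrca <- ape::getMRCA(tree, c(tips[i], tips[j]))
    rows[[length(rows) + 1L]] <- data.frame(
      species1 = tips[i], species2 = tips[j],
      n_parallel = sum(cl$pattern == "parallel"),
      n_reciprocal = sum(cl$pattern == "reciprocal"),
      distance = d[mrca], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Trend of parallel-loss fraction with time before speciation
#'
#' Pearson correlation between the per-species-pair fraction of parallel
#' losses (among independent double losses) and the distance between the
#' WGD and the pair's speciation node. Degenerate inputs (zero variance)
#' report NA.
#'
#' @param counts table from \code{\link{lossPatternCounts}}.
#' @return list \code{r, p, n} (NA when undefined).
#' @export
parallelTrend <- function(counts) {
  cc <- counts[counts$n_parallel + counts$n_reciprocal > 0, , drop = FALSE]
  frac <- cc$n_parallel / (cc$n_parallel + cc$n_reciprocal)
  if (nrow(cc) < 3 || sd(frac) == 0 || sd(cc$distance) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(cc)))
  ct <- cor.test(frac, cc$distance)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(cc))
}

#' Expression-biased loss statistics
#'
#' Two tests of predetermination by expression: (i) is loss of the
#' ortholog in species B enriched among the most expression-divergent
#' ohnolog pairs of species A (chi-square on the top-\code{top_q}
#' divergence stratum vs the rest); (ii) among losses in B, is the lost
#' gene the ortholog of A's lower-expressed copy more than half the time
#' (one-sample proportion test vs 0.5 with continuity correction).
#'
#' @param pairs data.frame with columns \code{expr_div} (expression-level
#'   divergence of the pair in A), \code{lost_in_b} (logical),
#'   \code{lost_low} (logical, lost gene orthologous to A's
#'   lower-expressed copy; NA when no loss).
#' @param top_q top divergence quantile, default 0.05.
#' @return list: loss rates overall and in the top stratum with the
#'   chi-square p; the low-expression-loss fraction with its
#'   proportion-test p, over all losses (\code{frac_low}, \code{prop_p})
#'   and within the top-divergence stratum (\code{frac_low_top},
#'   \code{prop_p_top}), where the shared (heritable) component of
#'   expression divergence dominates and the bias is strongest.
#' @export
expressionBiasedLoss <- function(pairs, top_q = 0.05) {
  thr <- quantile(pairs$expr_div, 1 - top_q, na.rm = TRUE)
  top <- pairs$expr_div >= thr
  tab <- table(top = factor(top, c(FALSE, TRUE)),
               lost = factor(pairs$lost_in_b, c(FALSE, TRUE)))
  p_chi <- tryCatch(chisq.test(tab)$p.value, warning = function(w)
    suppressWarnings(chisq.test(tab)$p.value), error = function(e) NA_real_)
  prop_arm <- function(sel) {
    n_lost <- sum(pairs$lost_in_b[sel], na.rm = TRUE)
    n_low <- sum(pairs$lost_low[sel] & pairs$lost_in_b[sel], na.rm = TRUE)
    if (n_lost == 0) return(c(NA_real_, NA_real_, 0))
    pt <- prop.test(n_low, n_lost, p = 0.5, correct = TRUE)
    c(n_low / n_lost, pt$p.value, n_lost)
  }
  all_arm <- prop_arm(rep(TRUE, nrow(pairs)))
  top_arm <- prop_arm(top)
  list(loss_rate_all = mean(pairs$lost_in_b, na.rm = TRUE),
       loss_rate_top = mean(pairs$lost_in_b[top], na.rm = TRUE),
       chisq_p = p_chi,
       frac_low = all_arm[1], prop_p = all_arm[2],
       frac_low_top = top_arm[1], prop_p_top = top_arm[2],
       n_pairs = nrow(pairs), n_lost = all_arm[3],
       n_lost_top = top_arm[3])
}

#' Survival points from simulator truth
#'
#' The exact per-node retained-pair counts recorded during the forward
#' simulation (free of the downward bias that Dollo parsimony incurs at
#' internal nodes whose few descendants all lost a copy), normalized to
#' the crown count, with distances measured from the crown.
#'
#' @param sim a \linkS4class{WGDSimulation}.
#' @return data.frame \code{node, distance, n_both, survival}.
#' @export
survivalFromTruth <- function(sim) {
  nb <- sim@truth$node_both
  .assert(!is.null(nb) && nrow(nb) > 0, "no node states recorded")
  crown <- nb$n_both[nb$distance == 0][1]
  nb$survival <- nb$n_both / crown
  nb
}

#' Presence matrix from simulator truth
#'
#' @param sim a \linkS4class{WGDSimulation}.
#' @return the pair-by-ingroup-species state matrix ("BOTH"/"ONE").
#' @export
presenceFromTruth <- function(sim) sim@truth$leaf_states

#' Expression-biased-loss table from simulator truth
#'
#' Assembles the input of \code{\link{expressionBiasedLoss}} for species
#' A (pairs retained in both copies there) against species B, using the
#' simulator's exact copy orthology.
#'
#' @param sim a \linkS4class{WGDSimulation}.
#' @param species_a,species_b ingroup species names.
#' @return data.frame \code{pair_id, expr_div, lost_in_b, lost_low}.
#' @export
biasedLossTable <- function(sim, species_a, species_b) {
  st <- sim@truth$leaf_states; sv <- sim@truth$leaf_surv
  ga <- sim@genomes[[species_a]]
  keep <- rownames(st)[st[, species_a] %in% "BOTH"]
  key <- paste0(ga$pair_id, ga$copy)
  eA <- expressionLevel(ga$fpkm[match(paste0(keep, "A"), key)])
  eB <- expressionLevel(ga$fpkm[match(paste0(keep, "B"), key)])
  lost <- st[keep, species_b] %in% "ONE"
  lost_copy <- ifelse(sv[keep, species_b] %in% "A", "B", "A")
  lost_low <- ifelse(lost,
                     ifelse(lost_copy == "A", eA < eB, eB < eA), NA)
  data.frame(pair_id = keep, expr_div = abs(eA - eB), lost_in_b = lost,
             lost_low = lost_low, stringsAsFactors = FALSE)
}
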