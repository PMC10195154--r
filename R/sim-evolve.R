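# Forward evolution of the doubled genome along the species tree:
# copy loss with expression/category-dependent hazards, a heritable
# per-pair asymmetry walk (predetermination), codon substitution,
# conversion tracts, single-gene duplications and translocations.

# mutate one CDS: Poisson numbers of synonymous / nonsynonymous events,
# sites chosen proportionally to their NG-style site counts
#' @noRd
.mutateCDS1 <- function(cds, tsyn, tnonsyn, tab) {
  cod <- .codonsOf(cds)
  s <- unname(tab$syn_sites[cod])
  ns <- rpois(1L, tsyn * sum(s))
  nn <- rpois(1L, tnonsyn * sum(3 - s))
  if (ns == 0L && nn == 0L) return(cds)
  for (k in seq_len(ns)) {
    i <- sample.int(length(cod), 1L, prob = s)
    nb <- tab$syn_nbrs[[cod[i]]]
    cod[i] <- nb[sample.int(length(nb), 1L)]
    s[i] <- tab$syn_sites[[cod[i]]]
  }
  for (k in seq_len(nn)) {
    i <- sample.int(length(cod), 1L, prob = 3 - s)
    nb <- tab$ns_nbrs[[cod[i]]]
    cod[i] <- nb[sample.int(length(nb), 1L)]
    s[i] <- tab$syn_sites[[cod[i]]]
  }
  paste(cod, collapse = "")
}

# one branch of evolution; `pairs` is NULL before the WGD; all processes
# on the branch share one lognormal rate multiplier (mean 1)
#' @noRd
.evolveBranch <- function(genes, pairs, t, child, cfg, tab, ceff, ev) {
  if (cfg@rate_sigma > 0 && t > 0)
    t <- t * rlnorm(1L, -cfg@rate_sigma^2 / 2, cfg@rate_sigma)
  n <- nrow(genes)
  # multiplicative expression drift
  if (cfg@expr_drift > 0 && t > 0)
    genes$fpkm <- genes$fpkm * exp(rnorm(n, 0, cfg@expr_drift * sqrt(t)))
  # codon substitution at per-lineage rate t/2 (so pairwise ohnolog Ks
  # equals tree distance from the WGD)
  if (cfg@sequences && t > 0)
    genes$cds <- vapply(genes$cds, .mutateCDS1, character(1),
                        tsyn = t / 2, tnonsyn = cfg@omega * t / 2,
                        tab = tab, USE.NAMES = FALSE)
  if (!is.null(pairs)) {
    if (cfg@predetermination_drift > 0 && t > 0)
      pairs$z <- pairs$z +
        rnorm(nrow(pairs), 0, cfg@predetermination_drift * sqrt(t))
    both <- which(pairs$state == "BOTH")
    if (length(both) && t > 0 && cfg@base_loss_rate > 0) {
      key <- paste0(genes$pair_id, genes$copy)
      iA <- match(paste0(pairs$pair_id[both], "A"), key)
      iB <- match(paste0(pairs$pair_id[both], "B"), key)
      eA <- expressionLevel(genes$fpkm[iA])
      eB <- expressionLevel(genes$fpkm[iB])
      h <- cfg@base_loss_rate *
        exp(-cfg@expr_beta * (eA + eB) / 2) *
        unname(ceff[genes$category[iA]])
      lose <- runif(length(both)) < 1 - exp(-h * t)
      if (any(lose)) {
        li <- both[lose]
        pA <- plogis(pairs$z[li] +
                       cfg@expression_copy_bias * (eB[lose] - eA[lose]))
        copy <- ifelse(runif(length(li)) < pA, "A", "B")
        pairs$state[li] <- "ONE"
        pairs$surv[li] <- ifelse(copy == "A", "B", "A")
        ev$events[[length(ev$events) + 1L]] <-
          data.frame(node = child, pair_id = pairs$pair_id[li],
                     lost_copy = copy, stringsAsFactors = FALSE)
        genes <- genes[!(paste0(genes$pair_id, genes$copy) %in%
                           paste0(pairs$pair_id[li], copy)), , drop = FALSE]
      }
    }
    # gene conversion: homogenize contiguous ancestral-rank tracts of
    # surviving pairs (copy A overwrites copy B)
    if (cfg@sequences && cfg@conversion_rate > 0 && t > 0) {
      for (sc in unique(genes$anc_scaffold[!is.na(genes$anc_scaffold)])) {
        for (k in seq_len(rpois(1L, cfg@conversion_rate * t))) {
          rmax <- max(genes$anc_rank[genes$anc_scaffold == sc], na.rm = TRUE)
          r0 <- sample.int(rmax + 1L, 1L) - 1L
          len <- 1L + rpois(1L, max(cfg@conversion_tract_len - 1, 0))
          key <- paste0(genes$pair_id, genes$copy)
          hit <- which(!is.na(genes$anc_scaffold) & genes$anc_scaffold == sc &
                         genes$anc_rank >= r0 & genes$anc_rank < r0 + len &
                         genes$copy == "B")
          hit <- hit[paste0(genes$pair_id[hit], "A") %in% key]
          if (length(hit)) {
            src <- match(paste0(genes$pair_id[hit], "A"), key)
            genes$cds[hit] <- genes$cds[src]
            ev$tracts[[length(ev$tracts) + 1L]] <-
              data.frame(node = child, anc_scaffold = sc, start = r0,
                         end = r0 + len - 1L, pair_id = genes$pair_id[hit],
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
    # single-gene duplications: copy one gene in place
    for (k in seq_len(rpois(1L, cfg@sgd_rate * t))) {
      i <- sample.int(nrow(genes), 1L)
      ev$sgd_n <- ev$sgd_n + 1L
      dup <- genes[i, , drop = FALSE]
      dup$id <- sprintf("sgd%04d", ev$sgd_n)
      dup$pair_id <- NA_character_; dup$copy <- NA_character_
      dup$anc_scaffold <- NA_character_; dup$anc_rank <- NA_integer_
      dup$pos <- dup$pos + 0.5
      genes <- rbind(genes, dup)
      ev$sgd[[length(ev$sgd) + 1L]] <-
        data.frame(node = child, source_id = genes$id[i], new_id = dup$id,
                   stringsAsFactors = FALSE)
    }
  }
  # translocations: move a random gene to a random position
  n_tr <- rpois(1L, cfg@translocation_rate * nrow(genes) * t)
  for (k in seq_len(n_tr)) {
    i <- sample.int(nrow(genes), 1L)
    sc <- sample(unique(genes$scaffold), 1L)
    rng <- range(genes$pos[genes$scaffold == sc])
    genes$scaffold[i] <- sc
    genes$pos[i] <- runif(1L, rng[1] - 1, rng[2] + 1)
  }
  list(genes = genes, pairs = pairs, t_eff = t)
}

#' @noRd
.finalizeLeaf <- function(genes, sp) {
  genes <- genes[order(genes$scaffold, genes$pos), , drop = FALSE]
  genes$rank <- .rank0(genes$pos, genes$scaffold)
  data.frame(gene_id = paste0(sp, "_", genes$id), species = sp,
             scaffold = paste0(sp, "_", genes$scaffold),
             rank = genes$rank, strand = genes$strand,
             pair_id = genes$pair_id, copy = genes$copy,
             anc_scaffold = genes$anc_scaffold, anc_rank = genes$anc_rank,
             fpkm = genes$fpkm, category = genes$category,
             cds = if ("cds" %in% names(genes)) genes$cds else NA_character_,
             stringsAsFactors = FALSE)
}

#' Evolve a genome along the species tree from the WGD onward
#'
#' Descends the species tree from its root; at the WGD node (the ingroup
#' crown) every gene is duplicated, after which each branch applies, in
#' order: expression drift, codon substitution, asymmetry-walk update and
#' copy loss (hazard \code{base_loss_rate * exp(-expr_beta * logE) *
#' category_effect}, the lost copy chosen from the heritable logistic
#' asymmetry weight), gene-conversion tracts, single-gene duplications,
#' and translocations. Pre-WGD branches (outgroups and the stem) evolve
#' sequences and expression only.
#'
#' @param tree species tree from \code{\link{simulateSpeciesTree}}.
#' @param ancestor pre-WGD gene table from
#'   \code{\link{simulateAncestralGenome}}.
#' @param cfg the \linkS4class{SimConfig}.
#' @return a \linkS4class{WGDSimulation}.
#' @export
evolvePostWGD <- function(tree, ancestor, cfg) {
  wgd <- attr(tree, "wgd_node")
  .assert(!is.null(wgd), "tree lacks a wgd_node attribute")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  tab <- if (cfg@sequences) .codonTables() else NULL
  cats <- sprintf("C%d", seq_len(cfg@n_categories))
  ceff <- setNames(cfg@category_effects, cats)
  ev <- new.env(parent = emptyenv())
  ev$events <- list(); ev$tracts <- list(); ev$sgd <- list(); ev$sgd_n <- 0L
  genomes <- vector("list", ntip)
  names(genomes) <- tree$tip.label
  states <- vector("list", ntip)

  anc <- ancestor
  anc$pair_id <- NA_character_; anc$copy <- NA_character_
  anc$anc_scaffold <- NA_character_; anc$anc_rank <- NA_integer_

  recurse <- function(node, genes, pairs, dist = 0, eff = 0) {
    if (node == wgd && is.null(pairs)) {
      w <- applyWGD(genes[, setdiff(names(genes),
                      c("pair_id", "copy", "anc_scaffold", "anc_rank"))])
      genes <- w$genome
      ev$anchors <- w$anchors
      pairs <- data.frame(pair_id = w$anchors$pair_id, state = "BOTH",
                          surv = NA_character_, z = 0,
                          stringsAsFactors = FALSE)
      stem <- attr(tree, "wgd_stem")
      if (!is.null(stem) && stem > 0) {
        # WGD-to-crown stem: shared evolution of the doubled genome;
        # stem losses are recorded on the crown node (shared by all)
        st <- .evolveBranch(genes, pairs, stem, wgd, cfg, tab, ceff, ev)
        genes <- st$genes; pairs <- st$pairs
        eff <- eff + st$t_eff
      }
    }
    if (!is.null(pairs))
      ev$nodes[[length(ev$nodes) + 1L]] <-
        data.frame(node = node, distance = dist,
                   n_both = sum(pairs$state == "BOTH"))
    if (node <= ntip)
      ev$depths[[length(ev$depths) + 1L]] <-
        data.frame(species = tree$tip.label[node], nominal = dist,
                   effective = eff, stringsAsFactors = FALSE)
    if (node <= ntip) {
      genomes[[node]] <<- .finalizeLeaf(genes, tree$tip.label[node])
      states[[node]] <<- pairs
      return(invisible(NULL))
    }
    for (ch in sort(tree$edge[tree$edge[, 1] == node, 2])) {
      t <- tree$edge.length[match(ch, tree$edge[, 2])]
      st <- .evolveBranch(genes, pairs, t, ch, cfg, tab, ceff, ev)
      recurse(ch, st$genes, st$pairs,
              if (is.null(pairs)) 0 else dist + t,
              if (is.null(pairs)) 0 else eff + st$t_eff)
    }
  }
  ev$nodes <- list(); ev$depths <- list()
  recurse(root, anc, NULL)

  ing <- attr(tree, "ingroup")
  pair_ids <- ev$anchors$pair_id
  leaf_states <- matrix(NA_character_, length(pair_ids), length(ing),
                        dimnames = list(pair_ids, ing))
  leaf_surv <- leaf_states
  for (sp in ing) {
    st <- states[[match(sp, tree$tip.label)]]
    leaf_states[, sp] <- st$state[match(pair_ids, st$pair_id)]
    leaf_surv[, sp] <- st$surv[match(pair_ids, st$pair_id)]
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(node = integer(0))
  new("WGDSimulation", config = cfg, tree = tree, wgdNode = as.integer(wgd),
      genomes = genomes,
      truth = list(anchors = ev$anchors, events = bind(ev$events),
                   leaf_states = leaf_states, leaf_surv = leaf_surv,
                   tracts = bind(ev$tracts), sgd = bind(ev$sgd),
                   node_both = bind(ev$nodes),
                   leaf_depth = bind(ev$depths), ancestor = ancestor))
}

#' Run a complete post-WGD simulation
#'
#' Convenience wrapper: seeds the RNG, generates the species tree and the
#' ancestral genome, and evolves it along the tree.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed integer seed for the whole simulation.
#' @return a \linkS4class{WGDSimulation}.
#' @export
#' @examples
#' sim <- simulatePostWGD(simConfig(n_genes = 50, n_scaffolds = 2,
#'   n_ingroup = 3, n_outgroup = 0, sequences = FALSE, sgd_rate = 0,
#'   translocation_rate = 0), seed = 1)
#' sim
simulatePostWGD <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulateSpeciesTree(cfg)
  anc <- simulateAncestralGenome(cfg)
  evolvePostWGD(tree, anc, cfg)
}

#' Replay ground-truth events to leaf states
#'
#' Derives each ingroup leaf's pair state purely from the recorded
#' per-branch loss events and compares nothing: callers can check the
#' result against \code{groundTruth(sim)$leaf_states}.
#'
#' @param sim a \linkS4class{WGDSimulation}.
#' @return character matrix (pairs x ingroup species) of replayed states.
#' @export
replayTruth <- function(sim) {
  tree <- sim@tree
  ing <- attr(tree, "ingroup")
  ev <- sim@truth$events
  pair_ids <- sim@truth$anchors$pair_id
  out <- matrix("BOTH", length(pair_ids), length(ing),
                dimnames = list(pair_ids, ing))
  root <- ape::Ntip(tree) + 1L
  wgd <- attr(tree, "wgd_node")
  for (sp in ing) {
    tip <- match(sp, tree$tip.label)
    path <- ape::nodepath(tree, root, tip)
    if (!(wgd %in% path)) path <- c(wgd, path)
    onpath <- ev$node %in% path
    if (any(onpath)) out[ev$pair_id[onpath], sp] <- "ONE"
  }
  out
}
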