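# High-level drivers chaining the per-module operations over a set of
# genomes, and simulator-truth evaluation utilities.

#' Run the cross-species analysis pipeline
#'
#' Chains the standard stages over a named list of gene tables:
#' per-species all-vs-all hits, anchors and paralogons; per-species-pair
#' cross hits; synteny-aware family clustering; candidate orthologs with
#' scaffold-score resolution of 1-to-2 relations; NJ gene trees per
#' family; ortholog groups; and cross-species paralogon chains.
#'
#' @param genomes named list of gene tables (gene_id, species, scaffold,
#'   rank, cds, fpkm).
#' @param ingroup species sharing the WGD (default: all).
#' @param outgroup pre-WGD species (excluded from paralogon detection;
#'   used only for outgroup ortholog assignment).
#' @param clade_a optional species subset used to root gene trees at the
#'   clade split (midpoint fallback).
#' @param k,min_shared,min_score hit-search parameters.
#' @param min_anchors,max_gap,max_block_gap paralogon parameters.
#' @param tree_distance distance for gene trees: "cds" (nucleotide,
#'   default; synonymous signal separates WGD copies even under strong
#'   purifying selection) or "protein".
#' @return list: \code{proteins}, \code{hits_within}, \code{hits_cross},
#'   \code{psets}, \code{families}, \code{orthologs} (per-pair resolved
#'   tables), \code{trees}, \code{groups}, \code{chains},
#'   \code{outgroup_orthologs}.
#' @export
crossSpeciesPipeline <- function(genomes, ingroup = names(genomes),
                                 outgroup = character(0), clade_a = NULL,
                                 k = 5L, min_shared = 2L, min_score = 50,
                                 min_anchors = 3L, max_gap = 5L,
                                 max_block_gap = 10L,
                                 tree_distance = c("cds", "protein")) {
  tree_distance <- match.arg(tree_distance)
  prots <- lapply(genomes, function(g)
    setNames(translateCDS(g$cds), g$gene_id))
  positions <- do.call(rbind, lapply(genomes, function(g)
    g[, c("gene_id", "scaffold", "rank")]))
  hits_within <- list(); psets <- list()
  for (sp in ingroup) {
    hw <- allVsAllHits(prots[[sp]], k = k, min_shared = min_shared,
                       min_score = min_score)
    hits_within[[sp]] <- hw
    psets[[sp]] <- detectParalogons(genomes[[sp]], hw,
                                    min_anchors = min_anchors,
                                    max_gap = max_gap,
                                    max_block_gap = max_block_gap)
  }
  hits_cross <- list()
  if (length(ingroup) > 1)
    for (i in seq_len(length(ingroup) - 1))
      for (j in (i + 1):length(ingroup)) {
        a <- ingroup[i]; b <- ingroup[j]
        hits_cross[[paste(a, b, sep = "|")]] <-
          allVsAllHits(prots[[a]], prots[[b]], k = k,
                       min_shared = min_shared, min_score = min_score)
      }
  hits_out <- list()
  for (o in outgroup) for (sp in ingroup)
    hits_out[[paste(o, sp, sep = "|")]] <-
      allVsAllHits(prots[[o]], prots[[sp]], k = k,
                   min_shared = min_shared, min_score = min_score)
  families <- clusterFamilies(c(hits_within, hits_cross), positions)
  out_orth <- if (length(hits_out))
    outgroupOrthologs(families, do.call(rbind, hits_out)) else NULL
  species_of <- setNames(positions$gene_id, positions$gene_id)
  species_of[] <- unlist(lapply(genomes, function(g) g$species),
                         use.names = FALSE)[
                           match(positions$gene_id,
                                 unlist(lapply(genomes, `[[`, "gene_id"),
                                        use.names = FALSE))]
  all_ids <- unlist(lapply(genomes, `[[`, "gene_id"), use.names = FALSE)
  all_cds <- setNames(unlist(lapply(genomes, `[[`, "cds"),
                             use.names = FALSE), all_ids)
  trees <- list(); groups <- list()
  for (f in unique(families$family_id)) {
    members <- families$gene_id[families$family_id == f]
    members <- members[species_of[members] %in% ingroup]
    if (length(members) < 3) next
    tr <- if (tree_distance == "cds") {
      sq <- all_cds[members]
      eq <- length(unique(nchar(sq))) == 1L
      buildGeneTree(cdsDistance(sq, align = !eq))
    } else {
      pr <- unlist(prots, use.names = FALSE)[
        match(members, unlist(lapply(prots, names), use.names = FALSE))]
      names(pr) <- members
      eq <- length(unique(nchar(pr))) == 1L
      buildGeneTree(pr, align = !eq)
    }
    tr <- if (!is.null(clade_a)) rootAtCladeSplit(tr, species_of, clade_a)
    else .midpointRoot(tr)
    trees[[f]] <- tr
    gg <- groupsFromGeneTree(tr, species_of)
    if (nrow(gg)) {
      gg$group_id <- paste(f, gg$group_id, sep = ".")
      groups[[f]] <- gg
    }
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group_id = character(0), gene_id = character(0))
  rownames(groups) <- NULL
  orthologs <- list()
  for (key in names(hits_cross)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    cand <- initialOrthologs(genomes[[ab[1]]], genomes[[ab[2]]],
                             families, hits_cross[[key]])
    gsc <- copyScaffoldScores(cand, all_cds)
    if (!nrow(gsc)) gsc <- scoreScaffolds(refineOrthologs(cand))
    cand <- refineOrthologs(cand, scores = gsc)
    orthologs[[key]] <- resolveOneToTwo(cand, gsc)
  }
  gene_par <- unlist(lapply(names(psets), function(sp) {
    loci <- psets[[sp]]@loci
    gp <- c(setNames(loci$paralogon_id, loci$gene1),
            setNames(loci$paralogon_id, loci$gene2))
    gp <- gp[!is.na(names(gp)) & names(gp) != ""]
    setNames(paste(sp, gp, sep = ":"), names(gp))
  }))
  chains <- chainParalogons(groups, gene_par)
  list(proteins = prots, hits_within = hits_within,
       hits_cross = hits_cross, psets = psets, families = families,
       orthologs = orthologs, outgroup_orthologs = out_orth,
       trees = trees, groups = groups, chains = chains,
       gene_paralogon = gene_par)
}

# combined truth lookup over all leaf genomes of a simulation
#' @noRd
.truthLookup <- function(sim) {
  all <- do.call(rbind, lapply(sim@genomes, function(g)
    g[, c("gene_id", "species", "pair_id", "copy", "anc_scaffold")]))
  rownames(all) <- all$gene_id
  all
}

#' Ortholog-call accuracy against simulator truth
#'
#' A 1-to-1 or resolved call is correct when both genes descend from the
#' same ancestral pair and are the same WGD copy; calls joining opposite
#' surviving copies count as correct only when the same-copy ortholog no
#' longer exists in the partner species.
#'
#' @param orthologs per-pair ortholog tables (list or single data.frame
#'   from \code{\link{resolveOneToTwo}}).
#' @param sim the \linkS4class{WGDSimulation} the genomes came from.
#' @return list \code{n, n_correct, accuracy}.
#' @export
truthOrthologAccuracy <- function(orthologs, sim) {
  if (is.data.frame(orthologs)) orthologs <- list(orthologs)
  lk <- .truthLookup(sim)
  n <- 0L; ok <- 0L
  for (ot in orthologs) {
    ot <- ot[ot$type %in% c("1to1", "2to2", "resolved"), , drop = FALSE]
    if (!nrow(ot)) next
    p1 <- lk[ot$gene_a, "pair_id"]; p2 <- lk[ot$gene_b, "pair_id"]
    c1 <- lk[ot$gene_a, "copy"]; c2 <- lk[ot$gene_b, "copy"]
    sp2 <- lk[ot$gene_b, "species"]
    same_pair <- !is.na(p1) & !is.na(p2) & p1 == p2
    same_copy <- same_pair & c1 == c2
    # opposite-copy link acceptable iff the matching copy is gone in B
    partner_alive <- paste(sp2, p1, c1) %in%
      paste(lk$species, lk$pair_id, lk$copy)
    good <- same_copy | (same_pair & !partner_alive)
    n <- n + nrow(ot); ok <- ok + sum(good)
  }
  list(n = n, n_correct = ok, accuracy = if (n) ok / n else NA_real_)
}

#' Paralogon-chain accuracy against simulator truth
#'
#' Each per-species paralogon is labelled by the majority ancestral
#' scaffold of its genes; a chained pair of adjacent nodes is correct
#' when the two labels agree.
#'
#' @param chains chain table from \code{\link{chainParalogons}}.
#' @param psets named list of \linkS4class{ParalogonSet}s.
#' @param sim the source \linkS4class{WGDSimulation}.
#' @return list \code{n_links, n_correct, accuracy}.
#' @export
truthChainAccuracy <- function(chains, psets, sim) {
  lk <- .truthLookup(sim)
  lab <- character(0)
  for (sp in names(psets)) {
    loci <- psets[[sp]]@loci
    genes <- c(loci$gene1, loci$gene2)
    par <- paste(sp, c(loci$paralogon_id, loci$paralogon_id), sep = ":")
    keep <- !is.na(genes)
    anc <- lk[genes[keep], "anc_scaffold"]
    for (p in unique(par[keep])) {
      tt <- table(anc[par[keep] == p])
      if (length(tt)) lab[p] <- names(sort(tt, decreasing = TRUE))[1]
    }
  }
  ch <- chains$chains
  n <- 0L; ok <- 0L
  for (cid in unique(ch$chain_id)) {
    nodes <- ch$node[ch$chain_id == cid]
    if (length(nodes) < 2) next
    for (i in seq_len(length(nodes) - 1)) {
      n <- n + 1L
      if (!is.na(lab[nodes[i]]) && !is.na(lab[nodes[i + 1]]) &&
          lab[nodes[i]] == lab[nodes[i + 1]]) ok <- ok + 1L
    }
  }
  list(n_links = n, n_correct = ok, accuracy = if (n) ok / n else NA_real_)
}
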