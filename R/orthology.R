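# Cross-species orthology: synteny-weighted candidate pairs, scaffold
# orthology scores, 1-to-2 resolution, outgroup assignment, gene-tree
# ortholog groups, and cross-species paralogon chaining.

#' Initial ortholog candidates between two species
#'
#' Within each gene family, cross-species best hits define candidate
#' ortholog pairs. Multiplicity is recorded from the family's per-species
#' gene counts: 1-to-1, 1-to-2 (one copy vs a retained WGD pair; both
#' pairings emitted, the mutual best flagged), 2-to-2 (mutual-best
#' pairings of the two copies), or multi.
#'
#' @param genome_a,genome_b gene tables of the two species.
#' @param families family table (\code{family_id, gene_id}).
#' @param hits cross-species hit table with \code{query} in species A and
#'   \code{subject} in species B.
#' @return data.frame \code{gene_a, gene_b, scaffold_a, scaffold_b, type,
#'   best, score}.
#' @export
initialOrthologs <- function(genome_a, genome_b, families, hits) {
  fam <- setNames(families$family_id, families$gene_id)
  h <- hits[!is.na(fam[hits$query]) & !is.na(fam[hits$subject]) &
              fam[hits$query] == fam[hits$subject], , drop = FALSE]
  if (!nrow(h))
    return(data.frame(family_id = character(0), gene_a = character(0),
                      gene_b = character(0), scaffold_a = character(0),
                      scaffold_b = character(0), type = character(0),
                      best = logical(0), score = numeric(0)))
  mb <- reciprocalBestHits(h)
  na <- table(fam[intersect(families$gene_id, genome_a$gene_id)])
  nb <- table(fam[intersect(families$gene_id, genome_b$gene_id)])
  rows <- list()
  for (f in unique(fam[mb$gene1])) {
    ca <- as.integer(na[f]); cb <- as.integer(nb[f])
    type <- if (ca == 1 && cb == 1) "1to1"
    else if (ca == 2 && cb == 2) "2to2"
    else if (min(ca, cb) == 1 && max(ca, cb) == 2) "1to2"
    else "multi"
    m <- mb[fam[mb$gene1] == f, , drop = FALSE]
    r <- data.frame(family_id = f, gene_a = m$gene1, gene_b = m$gene2,
                    type = type, best = TRUE, score = m$score,
                    stringsAsFactors = FALSE)
    if (type %in% c("1to2", "2to2")) {
      # emit the alternative pairings too, so copy resolution and
      # scaffold-score refinement see every combination
      ga <- intersect(names(fam)[fam == f], genome_a$gene_id)
      gb <- intersect(names(fam)[fam == f], genome_b$gene_id)
      for (x in ga) for (y in gb)
        if (!any(r$gene_a == x & r$gene_b == y)) {
          sc <- h$score[h$query == x & h$subject == y]
          r <- rbind(r, data.frame(family_id = f, gene_a = x, gene_b = y,
                                   type = type, best = FALSE,
                                   score = if (length(sc)) max(sc) else NA,
                                   stringsAsFactors = FALSE))
        }
    }
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out$scaffold_a <- genome_a$scaffold[match(out$gene_a, genome_a$gene_id)]
  out$scaffold_b <- genome_b$scaffold[match(out$gene_b, genome_b$gene_id)]
  out <- out[order(out$gene_a, out$gene_b),
             c("family_id", "gene_a", "gene_b", "scaffold_a", "scaffold_b",
               "type", "best", "score")]
  rownames(out) <- NULL
  out
}

#' Scaffold orthology scores
#'
#' The orthology score of a scaffold pair is the number of (best)
#' candidate ortholog pairs linking the two scaffolds.
#'
#' @param candidates table from \code{\link{initialOrthologs}}.
#' @return data.frame \code{scaffold_a, scaffold_b, score} (score >= 1).
#' @export
scoreScaffolds <- function(candidates) {
  cc <- candidates[candidates$best, , drop = FALSE]
  if (!nrow(cc))
    return(data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      score = integer(0)))
  ag <- aggregate(list(score = cc$gene_a),
                  by = list(scaffold_a = cc$scaffold_a,
                            scaffold_b = cc$scaffold_b), FUN = length)
  ag[order(ag$scaffold_a, ag$scaffold_b), , drop = FALSE]
}

#' Refine 2-to-2 copy assignment with scaffold orthology scores
#'
#' When speciation follows the WGD closely, alignment score alone barely
#' separates the true ortholog from the other WGD copy, so the
#' mutual-best pairing of a 2-to-2 family is noisy. Block-level signal
#' fixes this: scaffold orthology scores are computed from the current
#' candidate assignment, every 2-to-2 family is re-paired to maximise
#' the summed scaffold score of its two pairings, and the scores are
#' recomputed; a couple of iterations converge to the dominant
#' scaffold correspondence.
#'
#' @param candidates table from \code{\link{initialOrthologs}}.
#' @param n_iter refinement iterations, default 2 (ignored when
#'   \code{scores} is supplied).
#' @param scores optional fixed scaffold-score table (e.g. from
#'   \code{\link{groupScaffoldScores}}); when given, one re-pairing
#'   pass against it replaces the internal iteration.
#' @return the candidate table with 2-to-2 pairings updated.
#' @export
refineOrthologs <- function(candidates, n_iter = 2L, scores = NULL) {
  cand <- candidates
  sc_a <- c(setNames(cand$scaffold_a, cand$gene_a))
  sc_b <- c(setNames(cand$scaffold_b, cand$gene_b))
  fixed <- !is.null(scores)
  if (fixed) n_iter <- 1L
  for (it in seq_len(n_iter)) {
    if (!fixed) scores <- scoreScaffolds(cand)
    key <- paste(scores$scaffold_a, scores$scaffold_b)
    sc <- function(sa, sb) {
      i <- match(paste(sa, sb), key)
      ifelse(is.na(i), 0L, scores$score[i])
    }
    for (f in unique(cand$family_id[cand$type == "2to2"])) {
      rows <- which(cand$family_id == f)
      ga <- sort(unique(cand$gene_a[rows]))
      gb <- sort(unique(cand$gene_b[rows]))
      if (length(ga) != 2 || length(gb) != 2) next
      w1 <- sc(sc_a[ga[1]], sc_b[gb[1]]) + sc(sc_a[ga[2]], sc_b[gb[2]])
      w2 <- sc(sc_a[ga[1]], sc_b[gb[2]]) + sc(sc_a[ga[2]], sc_b[gb[1]])
      if (w1 == w2) next
      pair_b <- if (w1 > w2) gb else rev(gb)
      cand$best[rows] <- (cand$gene_a[rows] == ga[1] &
                            cand$gene_b[rows] == pair_b[1]) |
        (cand$gene_a[rows] == ga[2] & cand$gene_b[rows] == pair_b[2])
    }
  }
  cand <- cand[order(cand$gene_a, cand$gene_b), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Resolve 1-to-2 orthology to 1-to-1
#'
#' For every 1-to-2 candidate (one gene vs a retained WGD copy pair), the
#' ortholog is the copy whose scaffold pair carries the higher orthology
#' score; equal scores leave the relation unresolved (logged).
#'
#' @param candidates table from \code{\link{initialOrthologs}}.
#' @param scores table from \code{\link{scoreScaffolds}}.
#' @return data.frame \code{gene_a, gene_b, type} with type in
#'   \{1to1, 2to2, resolved, unresolved\}; unresolved rows keep the
#'   mutual-best pairing but are flagged.
#' @export
resolveOneToTwo <- function(candidates, scores) {
  key <- paste(scores$scaffold_a, scores$scaffold_b)
  sc <- function(sa, sb) {
    i <- match(paste(sa, sb), key)
    ifelse(is.na(i), 0L, scores$score[i])
  }
  keep <- candidates$type %in% c("1to1", "2to2") & candidates$best
  out <- candidates[keep, c("gene_a", "gene_b", "type"), drop = FALSE]
  oto <- candidates[candidates$type == "1to2", , drop = FALSE]
  if (nrow(oto)) {
    # group by the "1"-side gene (the side with a single copy)
    onea <- ave(seq_len(nrow(oto)), oto$gene_a, FUN = length) > 1
    oto$single <- ifelse(onea, oto$gene_a, oto$gene_b)
    for (g in unique(oto$single)) {
      rows <- oto[oto$single == g, , drop = FALSE]
      s <- sc(rows$scaffold_a, rows$scaffold_b)
      if (nrow(rows) < 2) {
        out <- rbind(out, rows[1, c("gene_a", "gene_b"), drop = FALSE] |>
                       cbind(type = "resolved"))
      } else if (max(s) == sort(s, decreasing = TRUE)[2]) {
        .plog("1-to-2 tie for %s left unresolved", g)
        best <- rows[which.max(rows$best), , drop = FALSE]
        out <- rbind(out, cbind(best[, c("gene_a", "gene_b")],
                                type = "unresolved"))
      } else {
        pickrow <- rows[which.max(s), , drop = FALSE]
        out <- rbind(out, cbind(pickrow[, c("gene_a", "gene_b")],
                                type = "resolved"))
      }
    }
  }
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Outgroup ortholog per family
#'
#' For each family, the outgroup gene with the maximum total hit score
#' against the family's members; families with no outgroup hits are
#' absent from the result.
#'
#' @param families family table over the ingroup genes.
#' @param hits hit table with outgroup genes as \code{query} and ingroup
#'   genes as \code{subject}.
#' @return data.frame \code{family_id, outgroup_gene, total_score}.
#' @export
outgroupOrthologs <- function(families, hits) {
  fam <- setNames(families$family_id, families$gene_id)
  h <- hits[!is.na(fam[hits$subject]), , drop = FALSE]
  if (!nrow(h))
    return(data.frame(family_id = character(0),
                      outgroup_gene = character(0),
                      total_score = numeric(0)))
  tot <- aggregate(list(total_score = h$score),
                   by = list(family_id = unname(fam[h$subject]),
                             outgroup_gene = h$query), FUN = sum)
  tot <- tot[order(tot$family_id, -tot$total_score, tot$outgroup_gene), ]
  out <- tot[!duplicated(tot$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Root a gene tree at the clade split
#'
#' Roots at the edge separating the gene copies of one species clade from
#' the rest when that split is clean (monophyletic); otherwise falls back
#' to midpoint rooting (logged). On single-WGD gene trees whose deepest
#' divergence is the copy-A/copy-B split, the midpoint fallback lands on
#' that split, which is what downstream ortholog grouping needs.
#'
#' @param tree unrooted gene tree.
#' @param species_of named vector mapping gene id to species.
#' @param clade_a species names of one clade.
#' @return rooted \code{ape::phylo}.
#' @export
rootAtCladeSplit <- function(tree, species_of, clade_a) {
  tips_a <- tree$tip.label[species_of[tree$tip.label] %in% clade_a]
  tips_b <- setdiff(tree$tip.label, tips_a)
  if (length(tips_a) && length(tips_b) &&
      ape::is.monophyletic(tree, tips_a)) {
    return(ape::root(tree, outgroup = tips_a, resolve.root = TRUE))
  }
  .plog("no clean clade split; midpoint rooting")
  .midpointRoot(tree)
}

#' Ortholog groups from a gene tree
#'
#' Starting from each sister pair of genes from different species (seeds
#' processed in deterministic order), the group absorbs the leaves of
#' successive sibling subtrees while every absorbed leaf adds a new
#' species; climbing stops as soon as a sibling subtree would duplicate a
#' species already in the group (or reuse a gene already grouped). Each
#' gene belongs to at most one group.
#'
#' @param tree gene tree (\code{ape::phylo}); reroot first with the
#'   clade-A/B split (or midpoint) for WGD-copy separation.
#' @param species_of named character vector mapping gene id to species.
#' @return data.frame \code{group_id, gene_id}.
#' @export
groupsFromGeneTree <- function(tree, species_of) {
  ntip <- ape::Ntip(tree)
  if (ntip < 2)
    return(data.frame(group_id = character(0), gene_id = character(0)))
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tipsets <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  labs <- tree$tip.label
  cherries <- which(vapply(seq_len(tree$Nnode) + ntip, function(v) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    length(ch) == 2 && all(ch <= ntip)
  }, logical(1))) + ntip
  ord <- order(vapply(cherries, function(v)
    .lexmin(labs[tipsets[[v]]]), character(1)))
  used <- character(0)
  groups <- list()
  for (v in cherries[ord]) {
    seed <- labs[tipsets[[v]]]
    if (any(seed %in% used)) next
    if (anyDuplicated(species_of[seed])) next
    g <- seed
    node <- v
    repeat {
      p <- parent[node]
      if (is.na(p)) break
      sibs <- setdiff(labs[tipsets[[p]]], labs[tipsets[[node]]])
      if (!length(sibs)) break
      if (any(sibs %in% used) ||
          any(species_of[sibs] %in% species_of[g]) ||
          anyDuplicated(species_of[sibs])) break
      g <- c(g, sibs)
      node <- p
    }
    used <- c(used, g)
    groups[[length(groups) + 1L]] <- sort(g)
  }
  if (!length(groups))
    return(data.frame(group_id = character(0), gene_id = character(0)))
  groups <- groups[order(vapply(groups, .lexmin, character(1)))]
  data.frame(group_id = rep(sprintf("G%05d", seq_along(groups)),
                            lengths(groups)),
             gene_id = unlist(groups, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Chain paralogons across species through the paralogon graph
#'
#' Nodes are per-species paralogons; an edge's weight is the number of
#' ortholog groups (gene trees) linking genes on the two paralogons.
#' Greedy path extraction: repeatedly take the heaviest edge with both
#' endpoints unused, then extend each end along its heaviest edge to an
#' unused node (ties lexicographic); every paralogon joins at most one
#' chain.
#'
#' @param groups ortholog-group table (\code{group_id, gene_id}).
#' @param gene_paralogon named character vector mapping gene id to a
#'   species-qualified paralogon id (NA genes are ignored).
#' @return list: \code{graph} (edge table \code{node1, node2, weight})
#'   and \code{chains} (\code{chain_id, node}).
#' @export
chainParalogons <- function(groups, gene_paralogon) {
  ew <- new.env(parent = emptyenv())
  for (gid in unique(groups$group_id)) {
    nodes <- unique(na.omit(unname(
      gene_paralogon[groups$gene_id[groups$group_id == gid]])))
    if (length(nodes) < 2) next
    nodes <- sort(nodes)
    for (i in seq_len(length(nodes) - 1)) for (j in (i + 1):length(nodes)) {
      k <- paste(nodes[i], nodes[j], sep = "\r")
      ew[[k]] <- (if (is.null(ew[[k]])) 0L else ew[[k]]) + 1L
    }
  }
  keys <- ls(ew)
  if (!length(keys))
    return(list(graph = data.frame(node1 = character(0),
                                   node2 = character(0),
                                   weight = integer(0)),
                chains = data.frame(chain_id = character(0),
                                    node = character(0))))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  graph <- data.frame(node1 = parts[, 1], node2 = parts[, 2],
                      weight = vapply(keys, function(k) ew[[k]],
                                      integer(1)),
                      stringsAsFactors = FALSE)
  graph <- graph[order(-graph$weight, graph$node1, graph$node2), ]
  rownames(graph) <- NULL
  used <- character(0)
  chains <- list()
  heaviest_ext <- function(node) {
    inc <- graph[(graph$node1 == node & !(graph$node2 %in% used)) |
                   (graph$node2 == node & !(graph$node1 %in% used)), ,
                 drop = FALSE]
    if (!nrow(inc)) return(NA_character_)
    other <- ifelse(inc$node1 == node, inc$node2, inc$node1)
    other[order(-inc$weight, other)][1]
  }
  for (i in seq_len(nrow(graph))) {
    u <- graph$node1[i]; v <- graph$node2[i]
    if (u %in% used || v %in% used) next
    chain <- c(u, v); used <- c(used, u, v)
    for (endpos in c("tail", "head")) {
      repeat {
        e <- if (endpos == "tail") chain[length(chain)] else chain[1]
        nxt <- heaviest_ext(e)
        if (is.na(nxt)) break
        chain <- if (endpos == "tail") c(chain, nxt) else c(nxt, chain)
        used <- c(used, nxt)
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }
  list(graph = graph,
       chains = data.frame(
         chain_id = rep(sprintf("CH%03d", seq_along(chains)),
                        lengths(chains)),
         node = unlist(chains, use.names = FALSE),
         stringsAsFactors = FALSE))
}


#' Ortholog pairs of one species pair implied by ortholog groups
#'
#' @param groups ortholog-group table (\code{group_id, gene_id}).
#' @param species_of named vector mapping gene id to species.
#' @param sp_a,sp_b the two species.
#' @return data.frame \code{gene_a, gene_b} (one row per group having
#'   exactly one gene in each species).
#' @export
groupOrthologPairs <- function(groups, species_of, sp_a, sp_b) {
  ga <- groups[species_of[groups$gene_id] == sp_a, , drop = FALSE]
  gb <- groups[species_of[groups$gene_id] == sp_b, , drop = FALSE]
  m <- merge(ga, gb, by = "group_id")
  data.frame(gene_a = m$gene_id.x, gene_b = m$gene_id.y,
             stringsAsFactors = FALSE)
}

#' Scaffold orthology scores from gene-tree ortholog groups
#'
#' Scores each scaffold pair by the number of ortholog groups linking
#' genes on the two scaffolds. Because groups separate WGD copies using
#' all species of the gene tree jointly, these scores stay informative
#' for species pairs whose divergence is close to the WGD itself, where
#' pairwise alignment scores carry almost no copy signal.
#'
#' @param groups ortholog-group table.
#' @param species_of named vector mapping gene id to species.
#' @param positions data.frame \code{gene_id, scaffold}.
#' @param sp_a,sp_b the two species.
#' @return data.frame \code{scaffold_a, scaffold_b, score}.
#' @export
groupScaffoldScores <- function(groups, species_of, positions, sp_a, sp_b) {
  pr <- groupOrthologPairs(groups, species_of, sp_a, sp_b)
  sc <- setNames(positions$scaffold, positions$gene_id)
  if (!nrow(pr))
    return(data.frame(scaffold_a = character(0),
                      scaffold_b = character(0), score = integer(0)))
  ag <- aggregate(list(score = pr$gene_a),
                  by = list(scaffold_a = unname(sc[pr$gene_a]),
                            scaffold_b = unname(sc[pr$gene_b])),
                  FUN = length)
  ag[order(ag$scaffold_a, ag$scaffold_b), , drop = FALSE]
}

#' Scaffold copy-correspondence scores from aggregated distance contrasts
#'
#' For species pairs that diverged very soon after the WGD, neither
#' pairwise scores nor individual gene-tree topologies separate the two
#' WGD copies reliably. The block-level signal does: for every 2-to-2
#' family with copies on scaffolds (u1, u2) in species A and (v1, v2) in
#' species B, the contrast d(a1,b2) + d(a2,b1) - d(a1,b1) - d(a2,b2) of
#' nucleotide distances is a noisy but unbiased vote for the scaffold
#' correspondence (u1-v1, u2-v2); summing the contrasts over all
#' families on the same scaffold quadruple makes one high-confidence
#' binary decision per quadruple. Returns the result as a scaffold-score
#' table usable by \code{\link{refineOrthologs}} and
#' \code{\link{resolveOneToTwo}}.
#'
#' @param candidates table from \code{\link{initialOrthologs}} (all
#'   combinations of 2-to-2 families must be present).
#' @param cds named character vector of coding sequences for both
#'   species.
#' @return data.frame \code{scaffold_a, scaffold_b, score} where score is
#'   the summed supporting contrast (0 for the rejected orientation).
#' @export
copyScaffoldScores <- function(candidates, cds) {
  sc_a <- c(setNames(candidates$scaffold_a, candidates$gene_a))
  sc_b <- c(setNames(candidates$scaffold_b, candidates$gene_b))
  acc <- new.env(parent = emptyenv())
  for (f in unique(candidates$family_id[candidates$type == "2to2"])) {
    rows <- which(candidates$family_id == f)
    ga <- sort(unique(candidates$gene_a[rows]))
    gb <- sort(unique(candidates$gene_b[rows]))
    if (length(ga) != 2 || length(gb) != 2) next
    u <- unname(sc_a[ga]); v <- unname(sc_b[gb])
    if (u[1] == u[2] || v[1] == v[2]) next
    sq <- cds[c(ga, gb)]
    if (anyNA(sq)) next
    d <- tryCatch(cdsDistance(sq, align =
                                length(unique(nchar(sq))) != 1L),
                  error = function(e) NULL)
    if (is.null(d)) next
    contrast <- d[ga[1], gb[2]] + d[ga[2], gb[1]] -
      d[ga[1], gb[1]] - d[ga[2], gb[2]]
    # canonical quadruple: order u, then express orientation for v
    if (u[1] > u[2]) { u <- rev(u); contrast <- -contrast }
    if (v[1] > v[2]) { v <- rev(v); contrast <- -contrast }
    key <- paste(u[1], u[2], v[1], v[2], sep = "\r")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + contrast
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(scaffold_a = character(0),
                      scaffold_b = character(0), score = numeric(0)))
  rows <- list()
  for (k in keys) {
    q <- strsplit(k, "\r", fixed = TRUE)[[1]]
    t <- acc[[k]]
    w <- abs(t)
    pair <- if (t >= 0) rbind(c(q[1], q[3]), c(q[2], q[4]))
    else rbind(c(q[1], q[4]), c(q[2], q[3]))
    anti <- if (t >= 0) rbind(c(q[1], q[4]), c(q[2], q[3]))
    else rbind(c(q[1], q[3]), c(q[2], q[4]))
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_a = c(pair[, 1], anti[, 1]),
      scaffold_b = c(pair[, 2], anti[, 2]),
      score = c(w, w, 0, 0), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- aggregate(list(score = out$score),
                   by = list(scaffold_a = out$scaffold_a,
                             scaffold_b = out$scaffold_b), FUN = sum)
  out[order(out$scaffold_a, out$scaffold_b), , drop = FALSE]
}
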