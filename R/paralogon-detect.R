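# Within-genome paralogon detection: WGD anchor pairs, colinear block
# merging, paralogon fusion, locus status calls, and ancestral (pre-WGD)
# gene-order reconstruction.

#' Find WGD anchor pairs within one genome
#'
#' Within-genome reciprocal best hits (self-hits excluded by
#' construction), annotated with scaffold/rank coordinates and put in
#' canonical order (gene1 < gene2).
#'
#' @param genome gene table with \code{gene_id, scaffold, rank}.
#' @param hits within-genome hit table (\code{\link{allVsAllHits}} on the
#'   genome's proteins).
#' @return data.frame \code{gene1, gene2, scaffold1, rank1, scaffold2,
#'   rank2}.
#' @export
findAnchors <- function(genome, hits) {
  rbh <- reciprocalBestHits(hits)
  if (!nrow(rbh))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      scaffold1 = character(0), rank1 = integer(0),
                      scaffold2 = character(0), rank2 = integer(0)))
  g1 <- pmin(rbh$gene1, rbh$gene2); g2 <- pmax(rbh$gene1, rbh$gene2)
  keep <- !duplicated(paste(g1, g2))
  g1 <- g1[keep]; g2 <- g2[keep]
  i1 <- match(g1, genome$gene_id); i2 <- match(g2, genome$gene_id)
  out <- data.frame(gene1 = g1, gene2 = g2,
                    scaffold1 = genome$scaffold[i1], rank1 = genome$rank[i1],
                    scaffold2 = genome$scaffold[i2], rank2 = genome$rank[i2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold1, out$rank1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge anchors into colinear paralogous blocks
#'
#' Greedy chaining per scaffold pair: anchors sorted along scaffold 1 are
#' chained while consecutive anchors are at most \code{max_gap} ranks
#' apart on both scaffolds and the rank mapping stays monotone (one
#' orientation flip allowed per block, i.e. orientation is fixed at the
#' second anchor). Chains with fewer than \code{min_anchors} anchors are
#' discarded.
#'
#' @param anchors anchor table from \code{\link{findAnchors}}.
#' @param min_anchors minimum anchors per block.
#' @param max_gap maximum rank gap on either scaffold.
#' @return list: \code{blocks} (block table with spans, counts,
#'   orientation) and \code{anchors} (input rows annotated with
#'   \code{block_id}, NA when unassigned).
#' @export
mergeBlocks <- function(anchors, min_anchors = 3L, max_gap = 5L) {
  anchors$block_id <- NA_character_
  blocks <- list()
  if (nrow(anchors)) {
    swap <- anchors$scaffold2 < anchors$scaffold1
    a <- anchors
    a[swap, c("scaffold1", "rank1", "scaffold2", "rank2")] <-
      a[swap, c("scaffold2", "rank2", "scaffold1", "rank1")]
    a$row <- seq_len(nrow(a))
    bid <- 0L
    for (sp in unique(paste(a$scaffold1, a$scaffold2))) {
      g <- a[paste(a$scaffold1, a$scaffold2) == sp, , drop = FALSE]
      g <- g[order(g$rank1), , drop = FALSE]
      chain <- list(g[1, , drop = FALSE]); orient <- 0L
      flush <- function(chain, orient) {
        ch <- do.call(rbind, chain)
        # a chain whose two segments overlap on one scaffold is a tandem
        # array, not a duplicated-segment pair
        self_overlap <- ch$scaffold1[1] == ch$scaffold2[1] &&
          min(ch$rank2) <= max(ch$rank1) && min(ch$rank1) <= max(ch$rank2)
        if (nrow(ch) >= min_anchors && !self_overlap) {
          bid <<- bid + 1L
          id <- sprintf("B%04d", bid)
          anchors$block_id[ch$row] <<- id
          blocks[[length(blocks) + 1L]] <<- data.frame(
            block_id = id, scaffold1 = ch$scaffold1[1],
            start1 = min(ch$rank1), end1 = max(ch$rank1),
            scaffold2 = ch$scaffold2[1],
            start2 = min(ch$rank2), end2 = max(ch$rank2),
            n_anchors = nrow(ch), orient = if (orient == 0L) 1L else orient,
            stringsAsFactors = FALSE)
        }
      }
      if (nrow(g) > 1) for (i in 2:nrow(g)) {
        last <- chain[[length(chain)]]
        d1 <- g$rank1[i] - last$rank1
        d2 <- g$rank2[i] - last$rank2
        ok <- d1 <= max_gap && abs(d2) <= max_gap && d2 != 0 &&
          (orient == 0L || sign(d2) == orient)
        if (ok) {
          if (orient == 0L) orient <- sign(d2)
          chain[[length(chain) + 1L]] <- g[i, , drop = FALSE]
        } else {
          flush(chain, orient)
          chain <- list(g[i, , drop = FALSE]); orient <- 0L
        }
      }
      flush(chain, orient)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(0), scaffold1 = character(0),
               start1 = integer(0), end1 = integer(0),
               scaffold2 = character(0), start2 = integer(0),
               end2 = integer(0), n_anchors = integer(0),
               orient = integer(0))
  list(blocks = blocks, anchors = anchors)
}

#' Fuse adjacent blocks into paralogons
#'
#' Blocks on the same scaffold pair with the same orientation whose spans
#' are within \code{max_block_gap} ranks on both scaffolds are
#' concatenated into one paralogon; every block belongs to exactly one
#' paralogon.
#'
#' @param blocks block table from \code{\link{mergeBlocks}}.
#' @param max_block_gap maximum rank gap between consecutive block spans.
#' @return the block table with a \code{paralogon_id} column.
#' @export
fuseParalogons <- function(blocks, max_block_gap = 10L) {
  blocks$paralogon_id <- NA_character_
  pid <- 0L
  for (sp in unique(paste(blocks$scaffold1, blocks$scaffold2,
                          blocks$orient))) {
    idx <- which(paste(blocks$scaffold1, blocks$scaffold2,
                       blocks$orient) == sp)
    idx <- idx[order(blocks$start1[idx])]
    prev <- NULL
    for (i in idx) {
      newp <- is.null(prev) ||
        blocks$start1[i] - blocks$end1[prev] > max_block_gap ||
        min(abs(blocks$start2[i] - blocks$end2[prev]),
            abs(blocks$end2[i] - blocks$start2[prev])) > max_block_gap
      if (newp) pid <- pid + 1L
      blocks$paralogon_id[i] <- sprintf("P%03d", pid)
      prev <- i
    }
  }
  blocks
}

# status calling: anchors inside blocks are RETAINED_BOTH; in-span
# non-anchor genes pair up through families (syntenic additions) or are
# SINGLE_COPY; order follows scaffold-1 ranks with scaffold-2-only genes
# interpolated through the nearest anchor
#' @noRd
.callLoci <- function(blocks, anchors, genome, families = NULL) {
  loci <- list()
  fam <- if (!is.null(families))
    setNames(families$family_id, families$gene_id) else NULL
  anchored <- c(anchors$gene1, anchors$gene2)
  for (b in seq_len(nrow(blocks))) {
    bl <- blocks[b, ]
    an <- anchors[!is.na(anchors$block_id) &
                    anchors$block_id == bl$block_id, , drop = FALSE]
    # canonical sides may be swapped relative to block definition
    s1 <- an$scaffold1 == bl$scaffold1
    r1 <- ifelse(s1, an$rank1, an$rank2)
    r2 <- ifelse(s1, an$rank2, an$rank1)
    ga <- ifelse(s1, an$gene1, an$gene2)
    gb <- ifelse(s1, an$gene2, an$gene1)
    rows <- data.frame(ord = as.numeric(r1), status = "RETAINED_BOTH",
                       gene1 = ga, gene2 = gb, stringsAsFactors = FALSE)
    in1 <- genome[genome$scaffold == bl$scaffold1 &
                    genome$rank >= bl$start1 & genome$rank <= bl$end1 &
                    !(genome$gene_id %in% anchored), , drop = FALSE]
    in2 <- genome[genome$scaffold == bl$scaffold2 &
                    genome$rank >= bl$start2 & genome$rank <= bl$end2 &
                    !(genome$gene_id %in% anchored), , drop = FALSE]
    # interpolate scaffold-2 ranks into scaffold-1 order via nearest anchor
    interp <- function(r2v) vapply(r2v, function(r) {
      i <- which.min(abs(r2 - r))
      r1[i] + bl$orient * (r - r2[i]) * 1e-3
    }, numeric(1))
    if (!is.null(fam) && nrow(in1) && nrow(in2)) {
      f1 <- fam[in1$gene_id]; f2 <- fam[in2$gene_id]
      m <- match(f1, f2)
      pairable <- !is.na(f1) & !is.na(m) & !duplicated(m)
      if (any(pairable)) {
        rows <- rbind(rows, data.frame(
          ord = as.numeric(in1$rank[pairable]), status = "RETAINED_BOTH",
          gene1 = in1$gene_id[pairable],
          gene2 = in2$gene_id[m[pairable]], stringsAsFactors = FALSE))
        in2 <- in2[-m[pairable], , drop = FALSE]
        in1 <- in1[!pairable, , drop = FALSE]
      }
    }
    if (nrow(in1))
      rows <- rbind(rows, data.frame(ord = as.numeric(in1$rank),
                                     status = "SINGLE_COPY",
                                     gene1 = in1$gene_id, gene2 = NA,
                                     stringsAsFactors = FALSE))
    if (nrow(in2))
      rows <- rbind(rows, data.frame(ord = interp(in2$rank),
                                     status = "SINGLE_COPY",
                                     gene1 = in2$gene_id, gene2 = NA,
                                     stringsAsFactors = FALSE))
    rows$block_id <- bl$block_id
    rows$paralogon_id <- bl$paralogon_id
    loci[[b]] <- rows[order(rows$ord), , drop = FALSE]
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(ord = numeric(0), status = character(0),
               gene1 = character(0), gene2 = character(0),
               block_id = character(0), paralogon_id = character(0))
  loci <- loci[order(loci$paralogon_id, loci$block_id, loci$ord), ,
               drop = FALSE]
  if (nrow(loci)) loci$locus_id <- sprintf("L%05d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci[, c("locus_id", "paralogon_id", "block_id", "ord", "status",
           "gene1", "gene2")]
}

#' Detect paralogons in one genome
#'
#' Full within-genome chain: anchor pairs (RBH), colinear block merging,
#' paralogon fusion, and per-locus status calling (anchors are
#' RETAINED_BOTH; in-span family-paired genes become syntenic-addition
#' RETAINED_BOTH loci; remaining in-span genes are SINGLE_COPY; isolated
#' genes outside every block stay unassigned).
#'
#' @param genome gene table (\code{gene_id, scaffold, rank}).
#' @param hits within-genome hit table.
#' @param families optional family table for syntenic additions.
#' @param min_anchors,max_gap,max_block_gap chaining parameters.
#' @return a \linkS4class{ParalogonSet}.
#' @export
detectParalogons <- function(genome, hits, families = NULL,
                             min_anchors = 3L, max_gap = 5L,
                             max_block_gap = 10L) {
  anch <- findAnchors(genome, hits)
  mb <- mergeBlocks(anch, min_anchors = min_anchors, max_gap = max_gap)
  blocks <- fuseParalogons(mb$blocks, max_block_gap = max_block_gap)
  mb$anchors$block_id <- mb$anchors$block_id
  loci <- .callLoci(blocks, mb$anchors, genome, families)
  new("ParalogonSet", species = genome$species[1], anchors = mb$anchors,
      blocks = blocks, loci = loci)
}

#' Reconstruct the pre-WGD ancestral gene order
#'
#' One representative gene per locus: the survivor at SINGLE_COPY loci, a
#' seeded random choice of the two copies at RETAINED_BOTH loci.
#' Ancestral order follows paralogon/block/locus order. Optionally,
#' anchors that fell outside every block and genes assigned to no locus
#' are appended as trailing loci so every surviving gene is represented
#' exactly once.
#'
#' @param pset a \linkS4class{ParalogonSet}.
#' @param genome the gene table the set was built from.
#' @param seed integer seed for the random copy choice.
#' @param include_unassigned append leftover anchors and isolated genes.
#' @return data.frame \code{locus_id, gene_id, ord, source}.
#' @export
reconstructAncestor <- function(pset, genome, seed = 0L,
                                include_unassigned = TRUE) {
  set.seed(seed)
  loci <- pset@loci
  pick <- ifelse(loci$status == "RETAINED_BOTH" & runif(nrow(loci)) < 0.5,
                 loci$gene2, loci$gene1)
  out <- data.frame(locus_id = loci$locus_id, gene_id = pick,
                    ord = seq_len(nrow(loci)), source = "paralogon",
                    stringsAsFactors = FALSE)
  if (include_unassigned) {
    used <- c(loci$gene1, loci$gene2)
    left <- pset@anchors[is.na(pset@anchors$block_id) &
                           !(pset@anchors$gene1 %in% used) &
                           !(pset@anchors$gene2 %in% used), , drop = FALSE]
    if (nrow(left)) {
      pick2 <- ifelse(runif(nrow(left)) < 0.5, left$gene2, left$gene1)
      out <- rbind(out, data.frame(
        locus_id = sprintf("LA%04d", seq_len(nrow(left))), gene_id = pick2,
        ord = nrow(out) + seq_len(nrow(left)), source = "loose_anchor",
        stringsAsFactors = FALSE))
      used <- c(used, left$gene1, left$gene2)
    }
    iso <- sort(setdiff(genome$gene_id, used))
    if (length(iso))
      out <- rbind(out, data.frame(
        locus_id = sprintf("LU%05d", seq_along(iso)), gene_id = iso,
        ord = nrow(out) + seq_along(iso), source = "unassigned",
        stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
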