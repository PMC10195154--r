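# Similarity search and gene-family machinery: global protein alignment
# scoring behind a k-mer prefilter, reciprocal best hits, synteny-aware
# family clustering, and distance-based (NJ) gene trees.

.ALN_GAP_OPEN <- 10
.ALN_GAP_EXT <- 0.5

#' Score one protein pair by global alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps.
#' Identity is the fraction of identical positions over aligned columns.
#'
#' @param protein_a,protein_b amino-acid sequences (character scalars).
#' @return one-row data.frame: \code{score}, \code{identity}.
#' @export
#' @examples
#' scorePair("MKVLA", "MKVLA")
scorePair <- function(protein_a, protein_b) {
  .assert(nchar(protein_a) > 0 && nchar(protein_b) > 0,
          "sequences must be nonempty")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", c(protein_a, protein_b))
  .assert(all(ok), "non-amino-acid characters in input")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(protein_a), Biostrings::AAStringSet(protein_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = .ALN_GAP_OPEN, gapExtension = .ALN_GAP_EXT)
  data.frame(score = Biostrings::score(aln),
             identity = Biostrings::pid(aln, type = "PID1") / 100)
}

# k-mer candidate pairs between two named protein vectors (or within one
# when b is NULL); k-mers present in > max_occ sequences are masked
#' @noRd
.kmerCandidates <- function(a, b = NULL, k = 4L, min_shared = 2L,
                            max_occ = 50L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  df <- function(x, side) {
    km <- lapply(x, kmers)
    data.frame(kmer = unlist(km, use.names = FALSE),
               id = rep(names(x), lengths(km)), side = side,
               stringsAsFactors = FALSE)
  }
  within <- is.null(b)
  da <- df(a, "a")
  db <- if (within) da else df(b, "b")
  keep <- names(which(table(da$kmer) <= max_occ))
  da <- da[da$kmer %in% keep, ]
  if (!within) {
    keep <- names(which(table(db$kmer) <= max_occ))
    db <- db[db$kmer %in% keep, ]
  }
  m <- merge(da[, 1:2], db[, 1:2], by = "kmer")
  if (within) m <- m[m$id.x < m$id.y, ]
  else m <- m[m$id.x != m$id.y, ]
  if (!nrow(m)) return(data.frame(q = character(0), s = character(0)))
  cnt <- aggregate(list(n = m$kmer), by = list(q = m$id.x, s = m$id.y),
                   FUN = length)
  cnt <- cnt[cnt$n >= min_shared, c("q", "s")]
  cnt[order(cnt$q, cnt$s), , drop = FALSE]
}

#' All-vs-all similarity hits with a k-mer prefilter
#'
#' Candidate pairs sharing at least \code{min_shared} length-\code{k}
#' amino-acid words are aligned globally (BLOSUM62, affine gaps);
#' unrelated pairs are never aligned. Within one set (\code{proteins_b}
#' NULL) self-hits are excluded and hits are emitted in both directions
#' so per-gene bests can be read off directly.
#'
#' @param proteins_a named character vector of protein sequences.
#' @param proteins_b optional second set for cross-set search.
#' @param k,min_shared prefilter word length and shared-word threshold.
#' @param min_score minimum alignment score to report (unrelated random
#'   proteins score far below this under BLOSUM62; homologs far above).
#' @return data.frame \code{query, subject, score, identity}.
#' @export
allVsAllHits <- function(proteins_a, proteins_b = NULL, k = 5L,
                         min_shared = 2L, min_score = 50) {
  cand <- .kmerCandidates(proteins_a, proteins_b, k = k,
                          min_shared = min_shared)
  if (!nrow(cand))
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), identity = numeric(0)))
  within <- is.null(proteins_b)
  getb <- if (within) proteins_a else proteins_b
  res <- vector("list", 0L)
  # batch: one subject vs its many candidate queries
  for (s in unique(cand$s)) {
    qs <- cand$q[cand$s == s]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins_a[qs]),
      Biostrings::AAStringSet(getb[[s]]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = .ALN_GAP_OPEN, gapExtension = .ALN_GAP_EXT)
    res[[length(res) + 1L]] <-
      data.frame(query = qs, subject = s, score = Biostrings::score(aln),
                 identity = Biostrings::pid(aln, type = "PID1") / 100,
                 stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, res)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (within)
    hits <- rbind(hits, data.frame(query = hits$subject,
                                   subject = hits$query,
                                   score = hits$score,
                                   identity = hits$identity,
                                   stringsAsFactors = FALSE))
  rownames(hits) <- NULL
  hits[order(hits$query, hits$subject), , drop = FALSE]
}

# best subject per query; ties broken lexicographically (and logged)
#' @noRd
.bestHits <- function(hits) {
  o <- order(hits$query, -hits$score, hits$subject)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query)
  tied <- h$query %in% h$query[duplicated(paste(h$query, h$score))][1]
  if (any(duplicated(paste(h$query, h$score)) & !duplicated(h$query)))
    .plog("best-hit ties broken lexicographically")
  h[first, , drop = FALSE]
}

#' Reciprocal best hits
#'
#' A pair (a, b) is kept iff b is a's best hit and a is b's best hit,
#' bests taken over the query and subject sides of \code{hits}
#' respectively. Score ties break lexicographically by gene id.
#'
#' @param hits hit table from \code{\link{allVsAllHits}}.
#' @return data.frame \code{gene1, gene2, score} (query-side gene first).
#' @export
reciprocalBestHits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      score = numeric(0)))
  bq <- .bestHits(hits)
  # a gene's best hit is read from its query rows; genes appearing only
  # as subjects (one-direction cross-species tables) use subject rows
  best <- bq[, c("query", "subject")]
  missing <- setdiff(unique(hits$subject), unique(hits$query))
  if (length(missing)) {
    sw <- hits[hits$subject %in% missing, , drop = FALSE]
    bs <- .bestHits(data.frame(query = sw$subject, subject = sw$query,
                               score = sw$score, stringsAsFactors = FALSE))
    best <- rbind(best, bs[, c("query", "subject")])
  }
  back <- setNames(best$subject, best$query)
  keep <- !is.na(back[bq$subject]) & back[bq$subject] == bq$query
  out <- data.frame(gene1 = bq$query[keep], gene2 = bq$subject[keep],
                    score = bq$score[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster genes into families
#'
#' Families are connected components of the reciprocal-best-hit graph,
#' optionally augmented with synteny-supported best hits: a (non-RBH)
#' best hit q -> s is added when a neighbour of q within \code{window}
#' ranks on q's scaffold has its own best hit on s's scaffold (conserved
#' local gene order). Deterministic: family ids follow the
#' lexicographically smallest member.
#'
#' @param hits a hit table, or a list of hit tables (one per species
#'   pair, within-species tables included); best hits and RBH are taken
#'   per table so each species pair contributes its own edges.
#' @param positions data.frame \code{gene_id, scaffold, rank} for synteny
#'   support (NULL disables the augmentation).
#' @param window neighbourhood radius in ranks.
#' @return data.frame \code{family_id, gene_id}.
#' @export
clusterFamilies <- function(hits, positions = NULL, window = 5L) {
  if (is.data.frame(hits)) hits <- list(hits)
  parts <- lapply(hits, function(h)
    .familyEdges(h, positions, window))
  edges <- do.call(rbind, parts)
  if (!nrow(edges))
    return(data.frame(family_id = character(0), gene_id = character(0)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  cmp <- igraph::components(g)
  mem <- split(names(cmp$membership), cmp$membership)
  mem <- mem[order(vapply(mem, .lexmin, character(1)))]
  data.frame(family_id = rep(sprintf("F%05d", seq_along(mem)),
                             lengths(mem)),
             gene_id = unlist(lapply(mem, sort), use.names = FALSE),
             stringsAsFactors = FALSE)
}

# RBH edges of one hit table, plus synteny-supported non-RBH best hits
#' @noRd
.familyEdges <- function(hits, positions = NULL, window = 5L) {
  rbh <- reciprocalBestHits(hits)
  edges <- rbh[, c("gene1", "gene2")]
  if (!is.null(positions) && nrow(hits)) {
    best <- .bestHits(hits)
    sc <- setNames(positions$scaffold, positions$gene_id)
    rk <- setNames(positions$rank, positions$gene_id)
    bh_sc <- setNames(sc[best$subject], best$query)
    in_rbh <- paste(best$query, best$subject) %in%
      c(paste(rbh$gene1, rbh$gene2), paste(rbh$gene2, rbh$gene1))
    for (i in which(!in_rbh)) {
      q <- best$query[i]; s <- best$subject[i]
      nb <- positions$gene_id[positions$scaffold == sc[q] &
                                abs(positions$rank - rk[q]) <= window &
                                positions$gene_id != q]
      supp <- bh_sc[nb]
      if (any(!is.na(supp) & supp == sc[s]))
        edges <- rbind(edges, data.frame(gene1 = q, gene2 = s,
                                         stringsAsFactors = FALSE))
    }
  }
  edges
}

#' Pairwise protein distance matrix
#'
#' p-distances (1 - fraction identical) either from global alignments or,
#' for equal-length ungapped sequence sets, from direct position-wise
#' comparison.
#'
#' @param proteins named character vector.
#' @param align align each pair first (set \code{FALSE} only for
#'   equal-length, indel-free sets).
#' @return symmetric numeric matrix.
#' @export
proteinDistance <- function(proteins, align = TRUE) {
  n <- length(proteins)
  ids <- names(proteins)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!align)
    .assert(length(unique(nchar(proteins))) == 1L,
            "align = FALSE needs equal-length sequences")
  spl <- if (!align) strsplit(unname(proteins), "") else NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (align) 1 - scorePair(proteins[[i]], proteins[[j]])$identity
    else mean(spl[[i]] != spl[[j]])
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Pairwise nucleotide distance matrix over coding sequences
#'
#' p-distances over CDS nucleotides. Synonymous sites dominate these
#' distances, so they retain phylogenetic signal under strong purifying
#' selection on the protein (where amino-acid distances are nearly
#' flat). Equal-length, indel-free sets are compared position-wise;
#' otherwise each pair is codon-aligned through its protein alignment.
#'
#' @param cds named character vector of coding sequences.
#' @param align align each pair through its protein alignment first.
#' @return symmetric numeric matrix.
#' @export
cdsDistance <- function(cds, align = TRUE) {
  n <- length(cds)
  ids <- names(cds)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!align) {
    .assert(length(unique(nchar(cds))) == 1L,
            "align = FALSE needs equal-length sequences")
    spl <- strsplit(unname(cds), "")
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- mean(spl[[i]] != spl[[j]])
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      al <- .codonAlign(cds[[i]], cds[[j]])
      p <- mean(strsplit(paste(al$a, collapse = ""), "")[[1]] !=
                  strsplit(paste(al$b, collapse = ""), "")[[1]])
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# Topological midpoint rooting: root at the internal node flanking the
# midpoint of the longest tip-to-tip path. Robust to zero-length and
# near-zero NJ edges (which trip phangorn's exact midpoint).
#' @noRd
.midpointRoot <- function(tr) {
  n <- ape::Ntip(tr)
  if (n <= 2 || ape::is.rooted(tr)) {
    if (n <= 2) return(tr)
  }
  D <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  path <- ape::nodepath(tr, ij[1], ij[2])
  el <- vapply(seq_len(length(path) - 1), function(k) {
    e <- which((tr$edge[, 1] == path[k] & tr$edge[, 2] == path[k + 1]) |
                 (tr$edge[, 1] == path[k + 1] & tr$edge[, 2] == path[k]))
    tr$edge.length[e[1]]
  }, numeric(1))
  cum <- cumsum(el)
  k <- which(cum >= cum[length(cum)] / 2)[1]
  cand <- c(path[k + 1], path[k])
  node <- cand[cand > n][1]
  if (is.na(node)) return(tr)
  out <- tryCatch(ape::root(tr, node = node, resolve.root = TRUE),
                  error = function(e) tr)
  out
}

#' Build a distance-based gene tree
#'
#' Neighbour-joining on a protein p-distance (or any supplied distance)
#' matrix. Families of fewer than 3 members return the trivial topology.
#' Leaf input order does not affect the topology (distances are
#' symmetric; leaves are processed in lexicographic order).
#'
#' @param x either a named character vector of protein sequences or a
#'   precomputed symmetric distance matrix.
#' @param align passed to \code{\link{proteinDistance}} when \code{x} is
#'   sequences.
#' @return an unrooted \code{ape::phylo}.
#' @export
buildGeneTree <- function(x, align = TRUE) {
  d <- if (is.matrix(x)) x else proteinDistance(x, align = align)
  ids <- sort(rownames(d))
  d <- d[ids, ids, drop = FALSE]
  .assert(length(ids) >= 2, "need at least 2 leaves")
  if (length(ids) == 2)
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", ids[1],
                                         d[1, 2] / 2, ids[2], d[1, 2] / 2)))
  tr <- ape::nj(as.dist(d))
  # clamp NJ's small negative branch lengths and normalize edge ordering
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::read.tree(text = ape::write.tree(tr))
}
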