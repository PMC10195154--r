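# Ancestral-genome generation and the WGD itself.

#' Simulate the pre-WGD ancestral genome
#'
#' Genes are laid out contiguously (0-based ranks) on near-equal-sized
#' scaffolds; CDS are random sense-codon sequences (no internal stops,
#' length a multiple of 3); expression is log-normal; functional
#' categories are drawn with the configured proportions.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed optional integer seed.
#' @return a gene table (data.frame): id, scaffold, pos (order key), rank,
#'   strand, fpkm, category, and cds when \code{cfg@sequences} is TRUE.
#' @export
simulateAncestralGenome <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg@n_genes
  ids <- sprintf("g%05d", seq_len(n))
  sc_sizes <- rep(n %/% cfg@n_scaffolds, cfg@n_scaffolds)
  if (n %% cfg@n_scaffolds > 0)
    sc_sizes[seq_len(n %% cfg@n_scaffolds)] <- sc_sizes[1] + 1L
  scaffold <- rep(sprintf("s%02d", seq_len(cfg@n_scaffolds)), sc_sizes)
  rank <- unlist(lapply(sc_sizes, function(k) seq_len(k) - 1L), use.names = FALSE)
  g <- data.frame(id = ids, scaffold = scaffold, pos = as.numeric(rank),
                  rank = rank, strand = sample(c("+", "-"), n, TRUE),
                  fpkm = rlnorm(n, cfg@fpkm_meanlog, cfg@fpkm_sdlog),
                  category = sample(sprintf("C%d", seq_len(cfg@n_categories)),
                                    n, TRUE, prob = cfg@category_probs),
                  stringsAsFactors = FALSE)
  if (cfg@sequences) {
    tab <- .codonTables()
    lens <- sample(seq(cfg@cds_len[1], cfg@cds_len[2]), n, TRUE)
    g$cds <- vapply(lens, function(L)
      paste(sample(tab$sense, L, TRUE), collapse = ""), character(1))
  }
  g
}

#' Apply the whole-genome duplication
#'
#' Duplicates every gene: copy A stays on scaffold \code{<s>a}, copy B on
#' the mirror scaffold \code{<s>b}, preserving gene order. Returns the
#' doubled genome plus the anchor truth table mapping each ancestral gene
#' to its two copies.
#'
#' @param genome a gene table from \code{\link{simulateAncestralGenome}}.
#' @return list with \code{genome} (doubled gene table with pair_id, copy,
#'   anc_scaffold, anc_rank columns) and \code{anchors} (pair_id,
#'   anc_scaffold, anc_rank).
#' @export
applyWGD <- function(genome) {
  .assert(nrow(genome) > 0, "genome is empty")
  mk <- function(copy) {
    g <- genome
    g$pair_id <- g$id
    g$copy <- copy
    g$anc_scaffold <- g$scaffold
    g$anc_rank <- g$rank
    g$id <- paste0(g$id, tolower(copy))
    g$scaffold <- paste0(g$scaffold, tolower(copy))
    g
  }
  doubled <- rbind(mk("A"), mk("B"))
  list(genome = doubled,
       anchors = data.frame(pair_id = genome$id,
                            anc_scaffold = genome$scaffold,
                            anc_rank = genome$rank,
                            stringsAsFactors = FALSE))
}

#' Plant recent single-gene duplications into a genome
#'
#' Inserts \code{n} duplicates of randomly chosen genes immediately after
#' their sources (ranks are recomputed), then applies codon substitutions
#' so that each planted pair sits at synonymous divergence \code{age}
#' (half on each copy). Used to validate single-gene-duplication calling
#' with known truth at a chosen age.
#'
#' @param genome a leaf gene table with \code{gene_id, scaffold, rank,
#'   cds}.
#' @param n number of duplications to plant.
#' @param age target pairwise Ks of each planted pair.
#' @param seed integer seed.
#' @return list: \code{genome} (updated table) and \code{pairs}
#'   (data.frame \code{gene1, gene2} of source and duplicate ids).
#' @export
plantSGDs <- function(genome, n = 30L, age = 0.2, seed = 1L) {
  set.seed(seed)
  .assert(!anyNA(genome$cds), "genome must carry sequences")
  tab <- .codonTables()
  idx <- sort(sample.int(nrow(genome), n))
  dup <- genome[idx, , drop = FALSE]
  dup$gene_id <- sprintf("%s_plant%03d", dup$gene_id, seq_len(n))
  key <- rbind(data.frame(ord = genome$rank, i = seq_len(nrow(genome))),
               data.frame(ord = genome$rank[idx] + 0.5,
                          i = nrow(genome) + seq_len(n)))
  out <- rbind(genome, dup)
  out <- out[key$i[order(key$ord)], , drop = FALSE]
  out <- out[order(out$scaffold), , drop = FALSE]
  out$rank <- .rank0(seq_len(nrow(out)), out$scaffold)
  src_ids <- genome$gene_id[idx]
  for (j in seq_len(n)) {
    for (id in c(src_ids[j], dup$gene_id[j])) {
      k <- match(id, out$gene_id)
      out$cds[k] <- .mutateCDS1(out$cds[k], age / 2,
                                0.05 * age / 2, tab)
    }
  }
  rownames(out) <- NULL
  list(genome = out,
       pairs = data.frame(gene1 = src_ids, gene2 = dup$gene_id,
                          stringsAsFactors = FALSE))
}
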