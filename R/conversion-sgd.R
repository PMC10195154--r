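# Gene-conversion detection (changepoints in Ks along paralogons) and
# single-gene duplication calling.

#' Ks profile of each paralogon
#'
#' The ordered series of Ks values over RETAINED_BOTH loci along each
#' paralogon (blocks concatenated in ancestral order); single-copy loci
#' carry no value and are skipped. Paralogons with no retained loci are
#' dropped (logged).
#'
#' @param pset a \linkS4class{ParalogonSet}.
#' @param ks_table data.frame \code{gene1, gene2, ks} (canonical gene
#'   order not required).
#' @return data.frame \code{paralogon_id, position, locus_id, gene1,
#'   gene2, ks}.
#' @export
ksProfile <- function(pset, ks_table) {
  key <- c(paste(ks_table$gene1, ks_table$gene2),
           paste(ks_table$gene2, ks_table$gene1))
  val <- rep(ks_table$ks, 2)
  loci <- pset@loci[pset@loci$status == "RETAINED_BOTH", , drop = FALSE]
  if (!nrow(loci)) {
    .plog("no retained loci; empty Ks profile")
    return(data.frame(paralogon_id = character(0), position = integer(0),
                      locus_id = character(0), gene1 = character(0),
                      gene2 = character(0), ks = numeric(0)))
  }
  loci$ks <- val[match(paste(loci$gene1, loci$gene2), key)]
  out <- lapply(split(loci, loci$paralogon_id), function(g) {
    g <- g[order(g$block_id, g$ord), , drop = FALSE]
    data.frame(paralogon_id = g$paralogon_id, position = seq_len(nrow(g)),
               locus_id = g$locus_id, gene1 = g$gene1, gene2 = g$gene2,
               ks = g$ks, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean-shift changepoints in a Ks series
#'
#' Exact penalized segmentation (optimal partitioning by dynamic
#' programming) under a Gaussian mean-shift cost: segment cost is its
#' residual sum of squares and each additional changepoint pays a
#' strengthened BIC penalty \code{4 * sigma^2 * log(n)} (sigma estimated
#' robustly from successive differences) unless supplied; the default
#' constant holds the false-positive rate of downstream conversion
#' flagging near the segment-test level on null profiles while keeping
#' near-full power for halving-size shifts of 5+ loci.
#'
#' @param x numeric series (profiles shorter than \code{min_len * 2}
#'   return no changepoints).
#' @param penalty per-changepoint penalty; NULL for the default.
#' @param min_len minimum segment length, default 3.
#' @return data.frame \code{index, direction, mean_left, mean_right}
#'   where \code{index} is the last position of the left segment.
#' @export
detectChangepoints <- function(x, penalty = NULL, min_len = 3L) {
  x <- as.numeric(x)
  n <- length(x)
  empty <- data.frame(index = integer(0), direction = character(0),
                      mean_left = numeric(0), mean_right = numeric(0))
  if (n < 2L * min_len) {
    .plog("profile too short for changepoint detection (n=%d)", n)
    return(empty)
  }
  if (is.null(penalty)) {
    sig <- median(abs(diff(x))) / (0.6745 * sqrt(2))
    if (!is.finite(sig) || sig == 0) sig <- sd(x) / 2
    if (!is.finite(sig) || sig == 0) return(empty)
    penalty <- 4 * sig^2 * log(n)
  }
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  costf <- function(a, b) {
    s <- cx[b + 1] - cx[a]; s2 <- cx2[b + 1] - cx2[a]
    s2 - s^2 / (b - a + 1)
  }
  FF <- rep(Inf, n + 1); FF[1] <- -penalty
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    if (t < min_len) next
    best <- Inf; barg <- 0L
    for (s in 0:(t - min_len)) {
      if (s != 0L && (s < min_len || !is.finite(FF[s + 1]))) next
      v <- FF[s + 1] + costf(s + 1, t) + penalty
      if (v < best - 1e-12) { best <- v; barg <- s }
    }
    FF[t + 1] <- best; prev[t + 1] <- barg
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  if (!length(cps)) return(empty)
  bounds <- c(0, cps, n)
  segm <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  data.frame(index = cps,
             direction = ifelse(diff(segm) < 0, "down", "up"),
             mean_left = segm[-length(segm)], mean_right = segm[-1])
}

#' Flag candidate gene-conversion segments
#'
#' Cuts a profile at its changepoints and flags segments whose Ks is
#' significantly lower than the rest of the profile (one-sided Wilcoxon
#' rank test at \code{alpha}); upward shifts are never flagged as
#' conversion.
#'
#' @param x the Ks series.
#' @param cps changepoint table from \code{\link{detectChangepoints}}.
#' @param alpha test level, default 0.05.
#' @return data.frame \code{start, end, mean, p, flagged}.
#' @export
flagConvertedSegments <- function(x, cps, alpha = 0.05) {
  n <- length(x)
  bounds <- c(0, cps$index, n)
  out <- lapply(seq_len(length(bounds) - 1), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    seg <- x[idx]; rest <- x[-idx]
    p <- if (length(rest) >= 2 && length(seg) >= 1 &&
             mean(seg) < mean(rest))
      suppressWarnings(wilcox.test(seg, rest,
                                   alternative = "less")$p.value)
    else 1
    data.frame(start = min(idx), end = max(idx), mean = mean(seg), p = p,
               flagged = p < alpha)
  })
  do.call(rbind, out)
}

#' Per-genome conversion summary
#'
#' Runs changepoint detection and segment flagging over every paralogon
#' profile of one species and reports the flagged fraction.
#'
#' @param profiles table from \code{\link{ksProfile}}.
#' @param min_len minimum testable profile length, default 10.
#' @param alpha segment-test level.
#' @param penalty optional changepoint penalty override.
#' @return list: \code{segments} (per-paralogon flagged segments),
#'   \code{n_testable}, \code{n_flagged}, \code{fraction}.
#' @export
conversionSummary <- function(profiles, min_len = 10L, alpha = 0.05,
                              penalty = NULL) {
  segs <- list(); n_testable <- 0L; n_flagged <- 0L
  for (pid in unique(profiles$paralogon_id)) {
    x <- profiles$ks[profiles$paralogon_id == pid]
    x <- x[is.finite(x)]
    if (length(x) < min_len) next
    n_testable <- n_testable + 1L
    fl <- flagConvertedSegments(x, detectChangepoints(x, penalty = penalty),
                                alpha = alpha)
    fl$paralogon_id <- pid
    if (any(fl$flagged)) n_flagged <- n_flagged + 1L
    segs[[length(segs) + 1L]] <- fl
  }
  list(segments = if (length(segs)) do.call(rbind, segs) else NULL,
       n_testable = n_testable, n_flagged = n_flagged,
       fraction = if (n_testable) n_flagged / n_testable else NA_real_)
}

#' Call recent single-gene duplications
#'
#' Ordered filters on within-genome reciprocal best hits: (1) self-hits
#' are excluded by construction; (2) pairs already annotated as
#' WGD-derived paralogs are removed (anchors assigned to a paralogous
#' block and retained-both loci of the paralogon set, plus anything in
#' \code{anchors} if supplied); (3) both genes must lie inside a
#' paralogon: within the per-scaffold span of some paralogon's blocks,
#' extended by \code{span_slack} ranks (block boundaries are fuzzy by
#' the anchor-chaining gap); (4) the pair's Ks must be below
#' \code{ks_max}. Removal counts per filter are attached as the
#' \code{"filters"} attribute.
#'
#' @param genome gene table with \code{gene_id, scaffold, rank, cds}.
#' @param hits within-genome hit table.
#' @param pset a \linkS4class{ParalogonSet} (WGD annotation and block
#'   spans).
#' @param anchors optional extra WGD-pair table (\code{gene1, gene2}) to
#'   exclude on top of the paralogon annotation.
#' @param ks_max synonymous-divergence ceiling, default 1.0.
#' @param span_slack rank slack added to paralogon spans, default 5.
#' @return data.frame \code{gene1, gene2, ks}.
#' @export
findSingleGeneDuplications <- function(genome, hits, pset, anchors = NULL,
                                       ks_max = 1.0, span_slack = 5L) {
  rbh <- reciprocalBestHits(hits)
  g1 <- pmin(rbh$gene1, rbh$gene2); g2 <- pmax(rbh$gene1, rbh$gene2)
  keep <- !duplicated(paste(g1, g2))
  cand <- data.frame(gene1 = g1[keep], gene2 = g2[keep],
                     stringsAsFactors = FALSE)
  n0 <- nrow(cand)
  pa <- pset@anchors[!is.na(pset@anchors$block_id), , drop = FALSE]
  lo <- pset@loci[pset@loci$status == "RETAINED_BOTH", , drop = FALSE]
  w1 <- c(pa$gene1, lo$gene1, if (!is.null(anchors)) anchors$gene1)
  w2 <- c(pa$gene2, lo$gene2, if (!is.null(anchors)) anchors$gene2)
  anch <- paste(pmin(w1, w2), pmax(w1, w2))
  cand <- cand[!(paste(cand$gene1, cand$gene2) %in% anch), , drop = FALSE]
  n1 <- nrow(cand)
  bl <- pset@blocks
  spans <- rbind(
    data.frame(par = bl$paralogon_id, sc = bl$scaffold1,
               lo = bl$start1, hi = bl$end1, stringsAsFactors = FALSE),
    data.frame(par = bl$paralogon_id, sc = bl$scaffold2,
               lo = bl$start2, hi = bl$end2, stringsAsFactors = FALSE))
  if (nrow(spans)) {
    key <- paste(spans$par, spans$sc)
    spans <- data.frame(
      sc = unname(tapply(spans$sc, key, `[`, 1)),
      lo = unname(tapply(spans$lo, key, min)) - span_slack,
      hi = unname(tapply(spans$hi, key, max)) + span_slack,
      stringsAsFactors = FALSE)
  }
  inblock <- function(g) {
    i <- match(g, genome$gene_id)
    sc <- genome$scaffold[i]; rk <- genome$rank[i]
    vapply(seq_along(g), function(j) any(
      spans$sc == sc[j] & spans$lo <= rk[j] & spans$hi >= rk[j]),
      logical(1))
  }
  if (nrow(cand))
    cand <- cand[inblock(cand$gene1) & inblock(cand$gene2), , drop = FALSE]
  n2 <- nrow(cand)
  cand$ks <- rep(NA_real_, nrow(cand))
  if (nrow(cand)) {
    cds <- setNames(genome$cds, genome$gene_id)
    cand$ks <- vapply(seq_len(nrow(cand)), function(i)
      estimateKsKa(cds[[cand$gene1[i]]], cds[[cand$gene2[i]]])$ks,
      numeric(1))
  }
  cand <- cand[is.finite(cand$ks) & cand$ks < ks_max, , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "filters") <- c(rbh_pairs = n0, non_anchor = n1,
                             in_block = n2, ks_pass = nrow(cand))
  .plog("SGD filters: %d RBH, %d non-anchor, %d in-block, %d Ks<%g",
        n0, n1, n2, nrow(cand), ks_max)
  cand
}
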