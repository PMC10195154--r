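# WGD placement by a vote over ladderized four-taxon gene subtrees
# (species-overlap duplication mapping).

#' Extract a ladder subtree for a taxon quartet
#'
#' Prunes a gene tree to the gene copies of four taxa (three clade taxa
#' plus one out-of-clade taxon). Returns NULL unless every taxon keeps at
#' least one copy.
#'
#' @param tree gene tree (\code{ape::phylo}, leaves = gene ids).
#' @param species_of named vector mapping gene id to species.
#' @param quartet character(4): taxa in ladder order
#'   \code{c(t1, t2, t3, outtaxon)}.
#' @return pruned \code{ape::phylo} or NULL.
#' @export
extractLadderSubtree <- function(tree, species_of, quartet) {
  .assert(length(quartet) == 4, "quartet must have 4 taxa")
  keep <- tree$tip.label[species_of[tree$tip.label] %in% quartet]
  sp <- unique(species_of[keep])
  if (!all(quartet %in% sp)) return(NULL)
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

# species-overlap duplication nodes: internal nodes whose child clades
# share at least one species; returns the spanned species set of the
# deepest (most inclusive) one, or NULL
#' @noRd
.deepestDuplication <- function(tree, species_of) {
  ntip <- ape::Ntip(tree)
  tipsets <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  best <- NULL; best_size <- -1L
  for (v in ntip + seq_len(tree$Nnode)) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(ch) < 2) next
    sets <- lapply(ch, function(c2)
      unique(species_of[tree$tip.label[tipsets[[c2]]]]))
    dup <- FALSE
    for (i in seq_len(length(sets) - 1)) for (j in (i + 1):length(sets))
      if (length(intersect(sets[[i]], sets[[j]]))) dup <- TRUE
    if (dup) {
      span <- unique(unlist(sets))
      if (length(span) > best_size) { best <- span; best_size <- length(span) }
    }
  }
  best
}

#' Vote WGD placement over ladder subtrees
#'
#' Each subtree is rooted on the out-of-clade taxon (when its copies are
#' monophyletic; otherwise midpoint) and its deepest species-overlap
#' duplication node is mapped to a branch of the fixed ladder topology
#' (((t1, t2), t3), out): the root branch when the duplication spans the
#' out-taxon, the clade base when it spans t1-t3, the (t1, t2) stem when
#' it spans exactly those two, a terminal branch for single-species
#' duplications; everything else (including duplication-free subtrees)
#' is unassigned. Percentages over all subtrees are banded as in
#' reporting convention: >= 50 orange, >= 25 blue, < 25 grey.
#'
#' @param subtrees list of pruned gene trees
#'   (\code{\link{extractLadderSubtree}} results; NULLs are dropped).
#' @param species_of named vector mapping gene id to species.
#' @param quartet the taxon quartet in ladder order.
#' @return data.frame \code{branch, n, percent, band}.
#' @export
votePlacement <- function(subtrees, species_of, quartet) {
  subtrees <- Filter(Negate(is.null), subtrees)
  .assert(length(subtrees) >= 1, "no subtrees to vote on")
  t1 <- quartet[1]; t2 <- quartet[2]; t3 <- quartet[3]; og <- quartet[4]
  branches <- c("root", "clade_base", "t1t2_base",
                paste0("terminal_", quartet), "unassigned")
  tally <- setNames(integer(length(branches)), branches)
  for (tr in subtrees) {
    tr2 <- tr
    ogtips <- tr$tip.label[species_of[tr$tip.label] %in% og]
    if (length(ogtips) < ape::Ntip(tr)) {
      tr2 <- tryCatch({
        if (ape::is.monophyletic(tr, ogtips) || length(ogtips) == 1)
          ape::root(tr, outgroup = ogtips, resolve.root = TRUE)
        else .midpointRoot(tr)
      }, error = function(e) .midpointRoot(tr))
    }
    span <- .deepestDuplication(tr2, species_of)
    lab <- if (is.null(span)) "unassigned"
    else if (og %in% span) "root"
    else if (all(c(t1, t2, t3) %in% span)) "clade_base"
    else if (setequal(span, c(t1, t2))) "t1t2_base"
    else if (length(span) == 1) paste0("terminal_", span)
    else "unassigned"
    tally[lab] <- tally[lab] + 1L
  }
  pct <- 100 * tally / sum(tally)
  data.frame(branch = branches, n = as.integer(tally), percent = pct,
             band = ifelse(pct >= 50, "orange",
                           ifelse(pct >= 25, "blue", "grey")),
             row.names = NULL, stringsAsFactors = FALSE)
}
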