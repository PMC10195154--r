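# Species-tree generation for the post-WGD simulator.

#' Generate (or parse) the species tree of a simulation
#'
#' Builds a rooted, strictly binary, ultrametric ingroup tree whose crown
#' node coincides with the WGD, with split heights concentrated near the
#' WGD (a radiation shortly after duplication, so internal branches are
#' short relative to terminal ones). Outgroup leaves attach below the WGD
#' node at 1.5x and 2x the WGD depth. Branch lengths are in expected-Ks
#' units. When \code{cfg@tree_newick} is non-empty that tree is used
#' instead (tips named \code{out*} are treated as outgroups).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used, so calls inside a seeded simulation stay reproducible).
#' @return an \code{ape::phylo} with attributes \code{ingroup},
#'   \code{outgroup} (species name vectors), \code{wgd_node} (the node
#'   number of the ingroup crown) and \code{wgd_stem} (the time between
#'   the WGD itself and the crown; the crown is the reference point of
#'   all downstream distances).
#' @export
simulateSpeciesTree <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nzchar(cfg@tree_newick)) {
    tr <- ape::read.tree(text = cfg@tree_newick)
    out <- grep("^out", tr$tip.label, value = TRUE)
  } else {
    n <- cfg@n_ingroup
    d <- cfg@depth
    crown <- d - cfg@wgd_stem
    ing <- sprintf("aur%02d", seq_len(n))
    # coalescent-style joining with radiation-era heights: all splits in
    # the oldest 45% of the crown age, crown pinned at depth - wgd_stem
    hts <- if (n > 2) sort(crown * (1 - 0.45 * rbeta(n - 2, 1, 3)))
    else numeric(0)
    hts <- c(hts, crown)
    lin <- data.frame(lab = ing, h = 0, stringsAsFactors = FALSE)
    for (h in hts) {
      i <- sort(sample.int(nrow(lin), 2))
      lab <- sprintf("(%s:%.12g,%s:%.12g)", lin$lab[i[1]],
                     h - lin$h[i[1]], lin$lab[i[2]], h - lin$h[i[2]])
      lin <- rbind(lin[-i, , drop = FALSE],
                   data.frame(lab = lab, h = h, stringsAsFactors = FALSE))
    }
    nwk <- lin$lab[1]
    out <- character(0)
    if (cfg@n_outgroup >= 1) {
      nwk <- sprintf("(%s:%.12g,out1:%.12g)", nwk, 1.5 * d - crown, 1.5 * d)
      out <- "out1"
    }
    if (cfg@n_outgroup >= 2) {
      nwk <- sprintf("(%s:%.12g,out2:%.12g)", nwk, 0.5 * d, 2 * d)
      out <- c("out1", "out2")
    }
    .assert(cfg@n_outgroup <= 2, "at most 2 outgroups are generated")
    tr <- ape::read.tree(text = paste0(nwk, ";"))
  }
  ing <- setdiff(tr$tip.label, out)
  .assert(length(ing) >= 2, "need at least 2 ingroup species")
  wgd <- ape::getMRCA(tr, ing)
  attr(tr, "ingroup") <- ing
  attr(tr, "outgroup") <- out
  attr(tr, "wgd_node") <- as.integer(wgd)
  attr(tr, "wgd_stem") <- if (nzchar(cfg@tree_newick)) 0 else cfg@wgd_stem
  tr
}
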