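# Codon-level machinery: genetic-code tables, translation, and the
# counting-method Ks/Ka estimator (Nei-Gojobori-style site/difference
# counting with Jukes-Cantor multiple-hit correction).

.codon_env <- new.env(parent = emptyenv())

# Lazily built lookup tables over the 61 sense codons:
#   syn_sites[codon]  : number of synonymous sites (per-position fraction sums)
#   syn_nbrs[[codon]] : single-nucleotide synonymous neighbours
#   ns_nbrs[[codon]]  : single-nucleotide nonsynonymous, non-stop neighbours
#' @noRd
.codonTables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  syn_sites <- setNames(numeric(length(sense)), sense)
  syn_nbrs <- setNames(vector("list", length(sense)), sense)
  ns_nbrs <- setNames(vector("list", length(sense)), sense)
  for (cd in sense) {
    aa <- gc[[cd]]
    sn <- character(0); nn <- character(0); s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        nb <- cd
        substr(nb, p, p) <- b
        if (gc[[nb]] == "*") next            # stop changes: nonsyn site weight,
        if (gc[[nb]] == aa) {                # excluded as mutation targets
          sn <- c(sn, nb); s <- s + 1 / 3
        } else nn <- c(nn, nb)
      }
    }
    syn_sites[cd] <- s
    syn_nbrs[[cd]] <- sn
    ns_nbrs[[cd]] <- nn
  }
  .codon_env$tab <- list(gc = gc, sense = sense, syn_sites = syn_sites,
                         syn_nbrs = syn_nbrs, ns_nbrs = ns_nbrs)
  .codon_env$pair <- new.env(parent = emptyenv())
  .codon_env$tab
}

# split a CDS string into its codon vector
#' @noRd
.codonsOf <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate coding sequences
#'
#' Translates CDS strings to protein strings under the standard genetic
#' code, dropping a terminal stop codon if present.
#'
#' @param cds character vector of nucleotide coding sequences, each a
#'   multiple of 3 in length.
#' @return character vector of amino-acid sequences.
#' @export
translateCDS <- function(cds) {
  .assert(all(nchar(cds) %% 3 == 0), "CDS length must be a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons by enumerating all mutational pathways, skipping paths through
# stop codons (all-stop-path pairs fall back to including them).
#' @noRd
.codonPairDiff <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste0(c1, c2)
  tab <- .codonTables()
  hit <- .codon_env$pair[[key]]
  if (!is.null(hit)) return(hit)
  gc <- tab$gc
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1L) list(pos) else {
    if (length(pos) == 2L) list(pos, rev(pos)) else {
      pp <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        pp[[length(pp) + 1L]] <- c(pos[i], pos[j], pos[setdiff(1:3, c(i, j))])
      pp
    }
  }
  tally <- function(allow_stop) {
    sd_tot <- 0; nd_tot <- 0; nvalid <- 0L
    for (ord in paths) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*" && !allow_stop) { ok <- FALSE; break }
        if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; nvalid <- nvalid + 1L }
    }
    if (nvalid == 0L) NULL else c(sd_tot, nd_tot) / nvalid
  }
  res <- tally(FALSE)
  if (is.null(res)) res <- tally(TRUE)
  .codon_env$pair[[key]] <- res
  res
}

# protein-guided codon alignment: align translated proteins globally and
# project the alignment back onto codons, dropping gapped columns
#' @noRd
.codonAlign <- function(cds_a, cds_b) {
  pa <- translateCDS(cds_a); pb <- translateCDS(cds_b)
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(pa),
                                       Biostrings::AAStringSet(pb),
                                       type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  sa <- strsplit(as.character(aln@pattern), "")[[1]]
  sb <- strsplit(as.character(aln@subject), "")[[1]]
  ca <- .codonsOf(cds_a); cb <- .codonsOf(cds_b)
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  list(a = ca[ia[keep]], b = cb[ib[keep]])
}

#' Synonymous and nonsynonymous divergence of a coding-sequence pair
#'
#' Counting-method estimator of Ks (synonymous substitutions per synonymous
#' site) and Ka (nonsynonymous substitutions per nonsynonymous site):
#' per-codon site counting and all-pathway difference averaging in the
#' Nei-Gojobori style, followed by the Jukes-Cantor multiple-hit
#' correction. When the proportion of differences reaches the correction's
#' domain boundary (p >= 3/4) the estimate is flagged as saturated.
#'
#' @param cds_a,cds_b nucleotide coding sequences (character scalars, length
#'   a multiple of 3). If \code{aligned = FALSE} the codons are aligned
#'   through a global protein alignment first and gapped codons dropped.
#' @param aligned set \code{TRUE} when the two CDS are already codon-aligned
#'   (equal length, no indels).
#' @return one-row \code{data.frame} with columns \code{ks}, \code{ka},
#'   \code{ka_ks} (NA when \code{ks} is 0 or unavailable) and
#'   \code{saturated}.
#' @export
#' @examples
#' estimateKsKa("ATGGCTAAA", "ATGGCTAAA", aligned = TRUE)
estimateKsKa <- function(cds_a, cds_b, aligned = FALSE) {
  .assert(nchar(cds_a) %% 3 == 0 && nchar(cds_b) %% 3 == 0,
          "CDS length must be a multiple of 3")
  tab <- .codonTables()
  if (aligned && nchar(cds_a) == nchar(cds_b)) {
    ca <- .codonsOf(cds_a); cb <- .codonsOf(cds_b)
  } else {
    al <- .codonAlign(cds_a, cds_b); ca <- al$a; cb <- al$b
  }
  ok <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[ok]; cb <- cb[ok]
  .assert(length(ca) > 0, "no comparable codons")
  S <- sum((tab$syn_sites[ca] + tab$syn_sites[cb]) / 2)
  N <- 3 * length(ca) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in which(ca != cb)) {
    d <- .codonPairDiff(ca[i], cb[i])
    sd_tot <- sd_tot + d[1]; nd_tot <- nd_tot + d[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- sd_tot / S; pn <- nd_tot / N
  ks <- jc(ps); ka <- jc(pn)
  saturated <- is.na(ks) || is.na(ka)
  data.frame(ks = ks, ka = ka,
             ka_ks = if (!saturated && ks > 0) ka / ks else NA_real_,
             saturated = saturated)
}
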