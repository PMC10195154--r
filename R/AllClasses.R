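# Central S4 containers: simulation configuration, simulation result,
# and the per-species paralogon set.

#' Simulation configuration for the post-WGD genome simulator
#'
#' Holds every tunable of the forward simulator: the pre-WGD genome size,
#' the species tree shape (or an explicit Newick string), copy-loss
#' hazards and their expression/category modifiers, the predetermination
#' (asymmetry) drift, conversion / single-gene-duplication /
#' translocation rates, and the codon substitution scheme. Branch lengths
#' are in expected-Ks units so that divergence and time share a scale.
#'
#' @slot n_genes pre-WGD gene count.
#' @slot n_scaffolds pre-WGD scaffold count.
#' @slot n_ingroup,n_outgroup leaf counts for the generated species tree
#'   (the ingroup shares the WGD; outgroups diverge before it).
#' @slot depth WGD-to-tip distance in expected-Ks units.
#' @slot wgd_stem time (Ks units) between the WGD and the ingroup crown
#'   (the first speciation); losses in this window are shared by all
#'   species and the corresponding pairs are single-copy at the crown.
#' @slot tree_newick optional explicit Newick species tree ("" = generate).
#' @slot base_loss_rate per-pair copy-loss hazard per unit Ks.
#' @slot expr_beta hazard multiplier exponent: h is proportional to
#'   exp(-expr_beta * log-expression).
#' @slot n_categories,category_probs,category_effects functional-category
#'   labels, their proportions, and per-category hazard multipliers.
#' @slot predetermination_drift rate at which the per-pair copy-asymmetry
#'   weight random-walks (logistic scale, per sqrt unit time).
#' @slot expr_drift sd of multiplicative log-expression drift per unit time.
#' @slot expression_copy_bias log-odds, per unit log-expression difference,
#'   that the lower-expressed copy is the one lost.
#' @slot conversion_rate gene-conversion tract initiations per paralogon per
#'   unit time; \code{conversion_tract_len} is the mean tract length (loci).
#' @slot sgd_rate single-gene duplications per genome per unit time.
#' @slot translocation_rate gene moves per gene per unit time.
#' @slot rate_sigma lognormal sd of a per-branch rate multiplier shared
#'   by all processes on that branch (substitution, loss, drift); 0
#'   (default) gives a strict clock, positive values couple lineage
#'   divergence rate and loss hazard.
#' @slot omega nonsynonymous/synonymous rate ratio of the codon scheme.
#' @slot cds_len codon-count range (min, max) of ancestral CDS.
#' @slot fpkm_meanlog,fpkm_sdlog log-normal expression parameters.
#' @slot sequences evolve codon sequences (disable for fast presence-only
#'   simulations of loss dynamics).
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_genes = "integer", n_scaffolds = "integer",
  n_ingroup = "integer", n_outgroup = "integer",
  depth = "numeric", wgd_stem = "numeric", tree_newick = "character",
  base_loss_rate = "numeric", expr_beta = "numeric",
  n_categories = "integer", category_probs = "numeric",
  category_effects = "numeric",
  predetermination_drift = "numeric", expr_drift = "numeric",
  expression_copy_bias = "numeric",
  conversion_rate = "numeric", conversion_tract_len = "numeric",
  sgd_rate = "numeric", translocation_rate = "numeric",
  rate_sigma = "numeric", omega = "numeric", cds_len = "integer",
  fpkm_meanlog = "numeric", fpkm_sdlog = "numeric",
  sequences = "logical"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@n_genes < object@n_scaffolds)
    msg <- c(msg, "n_genes must be >= n_scaffolds")
  if (object@n_ingroup < 2L) msg <- c(msg, "n_ingroup must be >= 2")
  rates <- c(object@base_loss_rate, object@conversion_rate, object@sgd_rate,
             object@translocation_rate, object@predetermination_drift,
             object@expr_drift, object@depth, object@omega,
             object@rate_sigma)
  if (any(rates < 0)) msg <- c(msg, "rates and depth must be >= 0")
  if (any(object@category_effects <= 0))
    msg <- c(msg, "category hazard multipliers must be > 0")
  if (length(object@category_probs) != object@n_categories ||
      abs(sum(object@category_probs) - 1) > 1e-8)
    msg <- c(msg, "category_probs must sum to 1 with one entry per category")
  if (object@cds_len[1] < 30L) msg <- c(msg, "cds_len minimum is 30 codons")
  if (object@wgd_stem < 0 || object@wgd_stem >= object@depth)
    msg <- c(msg, "wgd_stem must be in [0, depth)")
  if (length(msg)) msg else TRUE
})

#' Build a simulator configuration
#'
#' All arguments have defaults describing the study conditions the package
#' emulates: a pre-WGD ancestor of 5,000 genes on 20 scaffolds, a 13-leaf
#' ingroup radiating shortly after the WGD plus 2 pre-WGD outgroups at
#' unit WGD-to-tip depth, a copy-loss hazard of 0.7 per unit Ks weakly
#' decreasing with expression, strong purifying selection on protein
#' sequence (omega = 0.05), and rare conversion / single-gene-duplication
#' / translocation events. See the class documentation for slot meanings.
#'
#' @param n_genes,n_scaffolds,n_ingroup,n_outgroup,depth,wgd_stem,tree_newick
#'   see \linkS4class{SimConfig}.
#' @param base_loss_rate,expr_beta,n_categories,category_probs,category_effects
#'   loss-hazard model.
#' @param predetermination_drift,expr_drift,expression_copy_bias asymmetry
#'   model for which copy is lost.
#' @param conversion_rate,conversion_tract_len,sgd_rate,translocation_rate
#'   structural event rates.
#' @param rate_sigma,omega,cds_len,fpkm_meanlog,fpkm_sdlog,sequences
#'   lineage rate variation and sequence/expression model.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(n_genes = 5000, n_scaffolds = 20,
                      n_ingroup = 13, n_outgroup = 2,
                      depth = 1.0, wgd_stem = 0.1, tree_newick = "",
                      base_loss_rate = 0.7, expr_beta = 0.25,
                      n_categories = 8,
                      category_probs = rep(1 / n_categories, n_categories),
                      category_effects = rep(1, n_categories),
                      predetermination_drift = 1.0, expr_drift = 0.3,
                      expression_copy_bias = 0,
                      conversion_rate = 0.2, conversion_tract_len = 5,
                      sgd_rate = 28, translocation_rate = 0.01,
                      rate_sigma = 0, omega = 0.05, cds_len = c(100L, 300L),
                      fpkm_meanlog = 2, fpkm_sdlog = 1.5,
                      sequences = TRUE) {
  new("SimConfig",
      n_genes = as.integer(n_genes), n_scaffolds = as.integer(n_scaffolds),
      n_ingroup = as.integer(n_ingroup), n_outgroup = as.integer(n_outgroup),
      depth = depth, wgd_stem = wgd_stem, tree_newick = tree_newick,
      base_loss_rate = base_loss_rate, expr_beta = expr_beta,
      n_categories = as.integer(n_categories),
      category_probs = category_probs, category_effects = category_effects,
      predetermination_drift = predetermination_drift,
      expr_drift = expr_drift, expression_copy_bias = expression_copy_bias,
      conversion_rate = conversion_rate,
      conversion_tract_len = conversion_tract_len,
      sgd_rate = sgd_rate, translocation_rate = translocation_rate,
      rate_sigma = rate_sigma, omega = omega, cds_len = as.integer(cds_len),
      fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
      sequences = sequences)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes on", object@n_scaffolds,
      "scaffolds;", object@n_ingroup, "ingroup +", object@n_outgroup,
      "outgroup species; depth", object@depth, "Ks\n")
  cat("  loss hazard", object@base_loss_rate, "| expr beta",
      object@expr_beta, "| drift", object@predetermination_drift,
      "| sequences:", object@sequences, "\n")
})

#' Result of a post-WGD forward simulation
#'
#' @slot config the \linkS4class{SimConfig} used.
#' @slot tree the species tree (\code{ape::phylo}); the WGD coincides with
#'   the ingroup crown node (\code{wgdNode}).
#' @slot genomes named list (one per leaf species) of gene tables with
#'   columns gene_id, species, scaffold, rank, strand, pair_id, copy,
#'   fpkm, category and (when sequences are simulated) cds.
#' @slot truth ground-truth list: \code{anchors} (ancestral pair table),
#'   \code{events} (per-branch loss records), \code{leaf_states}
#'   (pair-by-species state matrix with surviving-copy annotation),
#'   \code{tracts} (conversion tracts), \code{sgd} (single-gene
#'   duplications), \code{ancestor} (pre-WGD gene table).
#' @exportClass WGDSimulation
setClass("WGDSimulation", representation(
  config = "SimConfig", tree = "ANY", wgdNode = "integer",
  genomes = "list", truth = "list"))

#' @describeIn WGDSimulation the species tree.
#' @param x,object a \code{WGDSimulation}.
#' @export
speciesTree <- function(x) x@tree

#' @describeIn WGDSimulation named list of leaf genome tables.
#' @export
leafGenomes <- function(x) x@genomes

#' @describeIn WGDSimulation the ground-truth list.
#' @export
groundTruth <- function(x) x@truth

setMethod("show", "WGDSimulation", function(object) {
  cat("WGDSimulation:", length(object@genomes), "leaf genomes,",
      nrow(object@truth$anchors), "ancestral pairs\n")
  st <- object@truth$leaf_states
  if (!is.null(st))
    cat("  mean leaf retention:",
        round(mean(colMeans(st == "BOTH")), 3), "\n")
})

#' Per-species paralogon set
#'
#' Colinear duplicated segments (paralogous blocks fused into paralogons)
#' detected within one genome, with per-locus retained/lost status.
#'
#' @slot species species identifier.
#' @slot anchors anchor-pair table (gene1, gene2, scaffolds, ranks, block).
#' @slot blocks block table with scaffold spans and anchor counts.
#' @slot loci locus table: locus_id, paralogon_id, block_id, ord (ancestral
#'   order), status (RETAINED_BOTH / SINGLE_COPY), gene1, gene2.
#' @exportClass ParalogonSet
setClass("ParalogonSet", representation(
  species = "character", anchors = "data.frame",
  blocks = "data.frame", loci = "data.frame"))

#' @describeIn ParalogonSet block table.
#' @param x,object a \code{ParalogonSet}.
#' @export
paralogonBlocks <- function(x) x@blocks

#' @describeIn ParalogonSet locus status table.
#' @export
paralogonLoci <- function(x) x@loci

#' @describeIn ParalogonSet anchor-pair table.
#' @export
paralogonAnchors <- function(x) x@anchors

setMethod("show", "ParalogonSet", function(object) {
  np <- length(unique(object@blocks$paralogon_id))
  cat("ParalogonSet [", object@species, "]: ", nrow(object@blocks),
      " blocks in ", np, " paralogons; ", nrow(object@loci), " loci (",
      sum(object@loci$status == "RETAINED_BOTH"), " retained-both)\n",
      sep = "")
})
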