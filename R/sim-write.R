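# On-disk dataset format: per-species FASTA/TSV files, the species tree,
# and the ground-truth JSON.

#' Write a simulated dataset to disk
#'
#' Emits, per species: protein and CDS FASTA, a gene-position table
#' (\code{gene_id scaffold rank strand}), an expression table
#' (\code{gene_id fpkm}) and a category table; globally: the species tree
#' (Newick) and the ground truth (JSON). Content is deterministic given
#' the simulation seed.
#'
#' @param sim a \linkS4class{WGDSimulation} (simulated with sequences).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
writeDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .assert(isTRUE(sim@config@sequences), "dataset export needs sequences")
  files <- character(0)
  for (sp in names(sim@genomes)) {
    g <- sim@genomes[[sp]]
    cds <- Biostrings::DNAStringSet(setNames(g$cds, g$gene_id))
    prot <- Biostrings::AAStringSet(setNames(translateCDS(g$cds), g$gene_id))
    f_cds <- file.path(dir, paste0(sp, ".cds.fa"))
    f_prot <- file.path(dir, paste0(sp, ".prot.fa"))
    Biostrings::writeXStringSet(cds, f_cds)
    Biostrings::writeXStringSet(prot, f_prot)
    f_pos <- file.path(dir, paste0(sp, ".genes.tsv"))
    write.table(g[, c("gene_id", "scaffold", "rank", "strand")], f_pos,
                sep = "\t", quote = FALSE, row.names = FALSE)
    f_expr <- file.path(dir, paste0(sp, ".expr.tsv"))
    write.table(data.frame(gene_id = g$gene_id, fpkm = g$fpkm), f_expr,
                sep = "\t", quote = FALSE, row.names = FALSE)
    f_cat <- file.path(dir, paste0(sp, ".category.tsv"))
    write.table(data.frame(gene_id = g$gene_id, category = g$category),
                f_cat, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f_cds, f_prot, f_pos, f_expr, f_cat)
  }
  f_tree <- file.path(dir, "tree.nwk")
  ape::write.tree(sim@tree, f_tree)
  truth <- sim@truth
  truth$leaf_states <- data.frame(pair_id = rownames(truth$leaf_states),
                                  truth$leaf_states, check.names = FALSE)
  truth$leaf_surv <- data.frame(pair_id = rownames(truth$leaf_surv),
                                truth$leaf_surv, check.names = FALSE)
  truth$ancestor$cds <- NULL
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(c(files, f_tree, f_truth))
}

#' Read a dataset written by \code{writeDataset}
#'
#' @param dir dataset directory.
#' @return list with \code{genomes} (per-species gene tables joining
#'   positions, expression, categories and sequences), \code{tree}
#'   (\code{ape::phylo}) and \code{truth} (list, if present).
#' @export
readDataset <- function(dir) {
  pos_files <- list.files(dir, "\\.genes\\.tsv$", full.names = TRUE)
  genomes <- list()
  for (f in pos_files) {
    sp <- sub("\\.genes\\.tsv$", "", basename(f))
    g <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    ex <- read.table(file.path(dir, paste0(sp, ".expr.tsv")), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    g$fpkm <- ex$fpkm[match(g$gene_id, ex$gene_id)]
    f_cat <- file.path(dir, paste0(sp, ".category.tsv"))
    if (file.exists(f_cat)) {
      ca <- read.table(f_cat, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      g$category <- ca$category[match(g$gene_id, ca$gene_id)]
    }
    cds <- Biostrings::readDNAStringSet(file.path(dir, paste0(sp, ".cds.fa")))
    g$cds <- as.character(cds)[g$gene_id]
    g$species <- sp
    genomes[[sp]] <- g
  }
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  f_truth <- file.path(dir, "truth.json")
  truth <- if (file.exists(f_truth)) jsonlite::read_json(f_truth,
                                                         simplifyVector = TRUE)
  list(genomes = genomes, tree = tree, truth = truth)
}
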