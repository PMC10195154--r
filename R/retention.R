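# Retention vs expression level and functional category.

#' Cross-species retention rate per outgroup (pre-WGD) gene
#'
#' For each outgroup gene, the number of ingroup species where both WGD
#' copies of its ortholog pair are retained divided by the number of
#' ingroup species with at least one ortholog. Genes with no ingroup
#' ortholog are excluded (not scored 0).
#'
#' @param states character matrix, rows = outgroup genes (or ancestral
#'   pairs), columns = ingroup species, cells "BOTH", "ONE" or NA (no
#'   ortholog / missing).
#' @return data.frame \code{gene_id, rate, n_species}.
#' @export
crossSpeciesRetention <- function(states) {
  n_with <- rowSums(matrix(states %in% c("BOTH", "ONE"), nrow(states)))
  n_both <- rowSums(matrix(states %in% "BOTH", nrow(states)))
  keep <- n_with > 0
  data.frame(gene_id = rownames(states)[keep],
             rate = n_both[keep] / n_with[keep],
             n_species = n_with[keep], stringsAsFactors = FALSE)
}

#' Binned retention profile
#'
#' Genes are split into \code{n_bins} equal-count bins by expression
#' level; each bin reports its mean retention rate with a
#' normal-approximation 95% confidence interval.
#'
#' @param expression numeric expression levels (one per gene).
#' @param rate retention rates (same length).
#' @param n_bins number of quantile bins, default 14.
#' @return data.frame \code{bin, expr_lo, expr_hi, mean_rate, ci_lo,
#'   ci_hi, n}.
#' @export
binnedRetention <- function(expression, rate, n_bins = 14L) {
  ok <- is.finite(expression) & is.finite(rate)
  expression <- expression[ok]; rate <- rate[ok]
  n <- length(rate)
  .assert(n >= n_bins, "fewer genes than bins")
  bin <- ceiling(order(order(expression, seq_len(n))) / (n / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    r <- rate[bin == b]; e <- expression[bin == b]
    se <- if (length(r) > 1) sd(r) / sqrt(length(r)) else 0
    data.frame(bin = b, expr_lo = min(e), expr_hi = max(e),
               mean_rate = mean(r), ci_lo = mean(r) - 1.96 * se,
               ci_hi = mean(r) + 1.96 * se, n = length(r))
  })
  do.call(rbind, out)
}

#' Category retention bias across two clades
#'
#' Per-category mean retention in each clade, the cross-clade Pearson
#' correlation of category means, and an expression-controlled
#' enrichment test per category: retention rates are permuted within
#' expression strata and each category's observed mean is compared with
#' its permutation null (two-sided), with Benjamini-Hochberg adjustment.
#'
#' @param categories character vector of per-gene category labels.
#' @param rate_a,rate_b per-gene retention rates in clade A and clade B.
#' @param expression per-gene expression levels (stratification control).
#' @param n_strata expression strata for the permutation, default 5.
#' @param n_perm permutations, default 999.
#' @return list: \code{table} (per-category means, enrichment p and q),
#'   \code{cross_clade_r}, \code{cross_clade_p}.
#' @export
categoryBias <- function(categories, rate_a, rate_b, expression,
                         n_strata = 5L, n_perm = 999L) {
  cats <- sort(unique(categories))
  .assert(length(cats) >= 2, "need at least 2 categories")
  ma <- vapply(cats, function(k) mean(rate_a[categories == k]), numeric(1))
  mb <- vapply(cats, function(k) mean(rate_b[categories == k]), numeric(1))
  ct <- cor.test(ma, mb)
  rate <- (rate_a + rate_b) / 2
  n <- length(rate)
  stratum <- ceiling(order(order(expression, seq_len(n))) / (n / n_strata))
  stratum <- pmin(pmax(stratum, 1L), n_strata)
  obs <- vapply(cats, function(k) mean(rate[categories == k]), numeric(1))
  null <- matrix(NA_real_, n_perm, length(cats),
                 dimnames = list(NULL, cats))
  for (p in seq_len(n_perm)) {
    perm <- rate
    for (s in seq_len(n_strata)) {
      i <- which(stratum == s)
      perm[i] <- rate[i][sample.int(length(i))]
    }
    null[p, ] <- vapply(cats, function(k) mean(perm[categories == k]),
                        numeric(1))
  }
  pval <- vapply(seq_along(cats), function(j) {
    lo <- (sum(null[, j] <= obs[j]) + 1) / (n_perm + 1)
    hi <- (sum(null[, j] >= obs[j]) + 1) / (n_perm + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  list(table = data.frame(category = cats, mean_a = ma, mean_b = mb,
                          mean_all = obs,
                          n = as.integer(table(categories)[cats]),
                          p = pval, q = p.adjust(pval, "BH"),
                          stringsAsFactors = FALSE),
       cross_clade_r = unname(ct$estimate), cross_clade_p = ct$p.value)
}
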