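# SNP-density enrichment in lncRNA loci against expression-matched coding
# controls, and per-SNP genotype-phenotype comparisons. SNP-in-gene uses the
# full gene span (not exons). Genome-wide association itself is out of
# scope: per-SNP association p-values are consumed as an input column.

#' Expression-matched coding control set
#'
#' Greedy nearest-neighbor matching without replacement on mean
#' log(FPKM + 1): lncRNA genes are processed in order of expression and each
#' takes the closest remaining coding gene.
#'
#' @param lnc_genes Character lncRNA gene ids (rows of `fpkm`).
#' @param coding_pool Character coding gene ids (must exceed `k`).
#' @param fpkm Gene x sample abundance matrix covering both sets.
#' @param k Number of controls (default one per lncRNA).
#' @return list with `controls` (gene ids), `mean_abs_delta` (matching
#'   quality on the log scale) and `deltas`.
#' @export
match_controls <- function(lnc_genes, coding_pool, fpkm, k = length(lnc_genes)) {
  if (length(coding_pool) < k) stopf("coding pool (%d) smaller than k = %d",
                                     length(coding_pool), k)
  miss <- setdiff(c(lnc_genes, coding_pool), rownames(fpkm))
  if (length(miss)) stopf("genes absent from fpkm: %s",
                          paste(head(miss, 5), collapse = ", "))
  target <- log(rowMeans(fpkm[lnc_genes, , drop = FALSE]) + 1)
  pool <- log(rowMeans(fpkm[coding_pool, , drop = FALSE]) + 1)
  ord <- order(target)
  avail <- rep(TRUE, length(pool))
  chosen <- character(k); deltas <- numeric(k)
  take <- head(ord, k)
  for (j in seq_along(take)) {
    i <- take[j]
    d <- abs(pool - target[i]); d[!avail] <- Inf
    b <- which.min(d)
    chosen[j] <- coding_pool[b]; deltas[j] <- d[b]; avail[b] <- FALSE
  }
  list(controls = chosen, mean_abs_delta = mean(deltas), deltas = deltas)
}

#' Density of trait-associated SNPs over a gene set
#'
#' Counts SNPs with association p below `alpha` whose position falls within
#' a gene span, per kb of summed gene length.
#'
#' @param genes `GRanges` of genes (with `gene_id`), non-empty.
#' @param snps data.frame with `snp_id`, `chrom`, `pos` and a per-trait
#'   association column `assoc_p_<trait>`.
#' @param trait Trait name (selects the `assoc_p_<trait>` column).
#' @param alpha Significance threshold in (0, 1); default 1e-5.
#' @return list of class `density_report`: `n_genes`, `total_kb`,
#'   `n_significant_snps`, `snps_per_kb`.
#' @export
snp_density <- function(genes, snps, trait = "survival", alpha = 1e-5) {
  stopifnot(is(genes, "GRanges"))
  if (length(genes) == 0L) stopf("empty gene set")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  col <- paste0("assoc_p_", trait)
  if (is.null(snps[[col]])) stopf("no association column %s", col)
  sig <- snps[snps[[col]] < alpha, , drop = FALSE]
  n_sig <- 0L
  if (nrow(sig)) {
    sgr <- GRanges(sig$chrom, IRanges(sig$pos, sig$pos))
    n_sig <- sum(countOverlaps(sgr, genes, ignore.strand = TRUE) > 0)
  }
  total_kb <- sum(width(genes)) / 1000
  structure(list(n_genes = length(genes), total_kb = total_kb,
                 n_significant_snps = n_sig,
                 snps_per_kb = n_sig / total_kb),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> %d genes (%.1f kb): %d significant SNPs, %.4f per kb\n",
              x$n_genes, x$total_kb, x$n_significant_snps, x$snps_per_kb))
  invisible(x)
}

#' Genotype-phenotype comparison for one SNP
#'
#' Two genotype classes: Welch t-test; three: one-way ANOVA. Missing
#' genotypes are dropped; every retained class needs at least 2 lines;
#' monomorphic SNPs are an error. Significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param genotypes Per-line allele counts (0/1/2 or factor-like), named by
#'   line; `NA` = missing.
#' @param trait Per-line trait values, aligned with `genotypes`.
#' @return list with `means` (per genotype class), `n`, `p`, `stars`.
#' @export
genotype_trait_test <- function(genotypes, trait) {
  stopifnot(length(genotypes) == length(trait))
  keep <- !is.na(genotypes) & !is.na(trait)
  g0 <- as.character(genotypes[keep]); y0 <- trait[keep]
  tab <- table(g0)
  ok_class <- names(tab)[tab >= 2L]
  sel <- g0 %in% ok_class
  g <- factor(g0[sel]); y <- y0[sel]
  k <- nlevels(g)
  if (k < 2L) stopf("monomorphic")
  p <- if (sd(y) == 0) {
    1   # no trait variation at all: no evidence of a genotype effect
  } else if (k == 2L) {
    t.test(y ~ g)$p.value
  } else {
    summary(aov(y ~ g))[[1]][["Pr(>F)"]][1]
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(means = tapply(y, g, mean), n = table(g), p = p, stars = stars)
}
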