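# Simplified co-expression module detection with eigengene / module-trait /
# module-membership statistics, and miRNA-bridged ceRNA network assembly.
#
# Module detection deliberately replaces the full WGCNA machinery
# (soft-threshold scan, topological overlap, dynamic tree cut) with its
# transparent core: signed adjacency ((1 + cor) / 2)^beta at fixed beta,
# plain adjacency dissimilarity, average-linkage clustering cut at a fixed
# height with a minimum module size. The analysis surface (eigengenes,
# module-trait correlations, MM/GS) is the one used downstream.

#' Detect co-expression modules
#'
#' @param expr Gene x sample expression matrix (DEGs, typically log-scale
#'   FPKM). Constant-expression genes are dropped with a warning.
#' @param min_module_size Minimum genes per module (default 30); smaller
#'   clusters are labeled `grey` (unassigned).
#' @param beta Soft-threshold power for the signed adjacency (default 6).
#' @param cut_height Dissimilarity height at which the average-linkage tree
#'   is cut (default 0.6).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `module_set`: `modules` (named membership vector,
#'   `grey` = unassigned), `eigengenes` (sample x module matrix), `sizes`.
#' @export
detect_modules <- function(expr, min_module_size = 30L, beta = 6,
                           cut_height = 0.6,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(expr) < 4L) stopf("need >= 4 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant-expression gene(s)", sum(sds == 0))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < min_module_size) stopf("fewer genes than min_module_size")
  cc <- cor(t(expr), method = method)
  adj <- ((1 + cc) / 2)^beta
  diss <- 1 - adj
  hc <- hclust(as.dist(diss), method = "average")
  grp <- cutree(hc, h = cut_height)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", nrow(expr))
  # deterministic labels: modules ordered by size, ties by first member name,
  # so the labeling is invariant to input row order
  ord <- order(-as.integer(sizes[keep]),
               vapply(keep, function(k) min(rownames(expr)[grp == as.integer(k)]),
                      character(1)))
  for (j in seq_along(ord))
    lab[grp == as.integer(keep[ord[j]])] <- paste0("M", j)
  names(lab) <- rownames(expr)
  egs <- NULL
  mods <- setdiff(sort(unique(lab)), "grey")
  if (length(mods)) {
    egs <- vapply(mods, function(m)
      eigengene(expr[lab == m, , drop = FALSE])$score, numeric(ncol(expr)))
    rownames(egs) <- colnames(expr)
  }
  structure(list(modules = lab, eigengenes = egs,
                 sizes = c(table(lab))),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- sum(names(x$sizes) != "grey")
  cat(sprintf("<module_set> %d module(s) + %d unassigned (grey) of %d genes\n",
              n_mod, x$sizes[["grey"]] %||% 0L, length(x$modules)))
  invisible(x)
}

#' Module eigengene (first principal component score)
#'
#' First principal component of the standardized member expression, scaled
#' to unit variance across samples, with the sign fixed so the mean
#' gene-eigengene correlation is nonnegative.
#'
#' @param expr_module Gene x sample matrix of module members (>= 2 genes).
#' @return list with `score` (per-sample eigengene), `var_explained`, `mm`
#'   (per-gene module membership = correlation with the eigengene).
#' @export
eigengene <- function(expr_module) {
  if (nrow(expr_module) < 2L) stopf("need >= 2 genes")
  z <- t(scale(t(expr_module)))
  if (anyNA(z)) stopf("constant-expression gene in module")
  sv <- svd(z)
  if (sv$d[1] <= 0) stopf("rank-0 module expression")
  score <- sv$v[, 1]
  score <- score / sd(score)
  mm <- as.numeric(cor(t(expr_module), score))
  if (mean(mm) < 0) { score <- -score; mm <- -mm }
  names(score) <- colnames(expr_module)
  list(score = score,
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       mm = setNames(mm, rownames(expr_module)))
}

#' Module-trait correlation matrix
#'
#' Pearson correlation (with test p) of each module eigengene with each
#' trait across samples; modules passing `|r| > r_min` and `p < alpha` for
#' a trait are retained. Constant traits are skipped with a warning.
#'
#' @param modules A [detect_modules()] result (or a sample x module
#'   eigengene matrix).
#' @param traits data.frame of per-sample traits (rows aligned with the
#'   eigengene samples; a `sample_id` column is used for alignment when
#'   present).
#' @param r_min,alpha Retention thresholds (defaults 0.2 and 0.05).
#' @return list with `r`, `p` (module x trait matrices) and `retained`
#'   (data.frame module/trait/r/p).
#' @export
module_trait <- function(modules, traits, r_min = 0.2, alpha = 0.05) {
  egs <- if (inherits(modules, "module_set")) modules$eigengenes else modules
  if (is.null(egs)) stopf("no modules to correlate")
  if (!is.null(traits$sample_id)) {
    rownames(traits) <- traits$sample_id
    traits <- traits[rownames(egs), setdiff(colnames(traits), "sample_id"),
                     drop = FALSE]
  }
  tn <- colnames(traits)
  keep <- vapply(tn, function(t) {
    v <- traits[[t]]
    if (!is.numeric(v) || anyNA(v)) return(FALSE)
    if (sd(v) == 0) { warnf("trait %s is constant; skipped", t); return(FALSE) }
    TRUE
  }, logical(1))
  tn <- tn[keep]
  if (!length(tn)) stopf("no usable traits")
  r <- p <- matrix(NA_real_, ncol(egs), length(tn),
                   dimnames = list(colnames(egs), tn))
  for (m in colnames(egs)) for (t in tn) {
    ht <- cor.test(egs[, m], traits[[t]])
    r[m, t] <- unname(ht$estimate); p[m, t] <- ht$p.value
  }
  sel <- which(abs(r) > r_min & p < alpha, arr.ind = TRUE)
  retained <- data.frame(module = rownames(r)[sel[, 1]],
                         trait = colnames(r)[sel[, 2]],
                         r = r[sel], p = p[sel], stringsAsFactors = FALSE)
  list(r = r, p = p, retained = retained)
}

#' Module membership vs gene significance
#'
#' MM = per-gene correlation with the module eigengene; GS = per-gene
#' correlation with the trait across samples; reports cor(MM, GS) with test
#' p and a flag at `|r| > 0.3`.
#'
#' @param expr_module Gene x sample matrix of module members (>= 3 genes).
#' @param trait Per-sample trait vector.
#' @param r_flag Threshold for the significance flag (default 0.3).
#' @return list with `mm`, `gs`, `cor_mm_gs`, `p`, `flag`.
#' @export
mm_gs <- function(expr_module, trait, r_flag = 0.3) {
  if (nrow(expr_module) < 3L) stopf("module size < 3")
  eg <- eigengene(expr_module)
  gs <- as.numeric(cor(t(expr_module), trait))
  ht <- cor.test(eg$mm, gs)
  list(mm = eg$mm, gs = setNames(gs, rownames(expr_module)),
       cor_mm_gs = unname(ht$estimate), p = ht$p.value,
       flag = abs(unname(ht$estimate)) > r_flag)
}

## ---- ceRNA network ---------------------------------------------------------

CERNA_INTERACTIONS <- c("cleavage", "translation_inhibition", "mimic")

validate_mir_table <- function(tab, what) {
  need <- c("rna_id", "rna_type", "mirna_id", "interaction")
  if (!all(need %in% colnames(tab)))
    stopf("%s table needs columns %s", what, paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$interaction), CERNA_INTERACTIONS)
  if (length(bad)) stopf("unknown interaction type: %s", paste(bad, collapse = ", "))
  tab
}

#' Assemble the miRNA-bridged ceRNA network
#'
#' The network is the union of typed RNA-miRNA edges; a bridge triple
#' (ncRNA, miRNA, mRNA) is emitted iff the ncRNA-miRNA and miRNA-mRNA
#' edges both exist for that miRNA.
#'
#' @param lnc_mir,circ_mir,mrna_mir data.frames with columns `rna_id`,
#'   `rna_type`, `mirna_id`, `interaction` (types restricted to cleavage /
#'   translation_inhibition / mimic).
#' @return Object of class `cerna_network`: `edges`, `bridges` (data.frame
#'   ncrna_id/ncrna_type/mirna_id/mrna_id), `stats` (see [network_stats()]).
#' @export
build_cerna <- function(lnc_mir, circ_mir, mrna_mir) {
  lnc_mir <- validate_mir_table(lnc_mir, "lnc_mir")
  circ_mir <- validate_mir_table(circ_mir, "circ_mir")
  mrna_mir <- validate_mir_table(mrna_mir, "mrna_mir")
  edges <- rbind(lnc_mir, circ_mir, mrna_mir)
  edges <- edges[order(edges$rna_id, edges$mirna_id), , drop = FALSE]
  rownames(edges) <- NULL
  nc <- rbind(lnc_mir, circ_mir)
  mr <- mrna_mir
  bridges <- merge(nc[, c("rna_id", "rna_type", "mirna_id")],
                   mr[, c("rna_id", "mirna_id")],
                   by = "mirna_id", suffixes = c("_nc", "_m"))
  bridges <- data.frame(ncrna_id = bridges$rna_id_nc,
                        ncrna_type = bridges$rna_type,
                        mirna_id = bridges$mirna_id,
                        mrna_id = bridges$rna_id_m,
                        stringsAsFactors = FALSE)
  bridges <- unique(bridges)
  bridges <- bridges[order(bridges$ncrna_id, bridges$mirna_id, bridges$mrna_id), ,
                     drop = FALSE]
  rownames(bridges) <- NULL
  structure(list(edges = edges, bridges = bridges,
                 stats = network_stats(edges)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<cerna_network> %d lncRNAs, %d circRNAs, %d mRNAs, %d miRNAs; %d edges, %d bridges\n",
              s$n_lncRNA, s$n_circRNA, s$n_mRNA, s$n_miRNA, s$n_edges,
              nrow(x$bridges)))
  invisible(x)
}

#' Node and edge counts of a ceRNA edge list
#'
#' @param edges data.frame with `rna_id`, `rna_type`, `mirna_id`.
#' @return list with distinct node counts per RNA type, miRNA count, edge
#'   count, and the miRNA degree distribution.
#' @export
network_stats <- function(edges) {
  if (nrow(edges) == 0L) stopf("non-empty edge list required")
  cnt <- function(ty) length(unique(edges$rna_id[edges$rna_type == ty]))
  deg <- table(edges$mirna_id)
  list(n_lncRNA = cnt("lncRNA"), n_circRNA = cnt("circRNA"),
       n_mRNA = cnt("mRNA"), n_miRNA = length(unique(edges$mirna_id)),
       n_edges = nrow(unique(edges[, c("rna_id", "mirna_id")])),
       mirna_degree = deg)
}
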