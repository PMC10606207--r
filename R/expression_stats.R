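# Differential-expression classification, Shannon-entropy expression
# specificity, specific-expression calling and the contingency/proportion
# statistics used throughout the analysis.
#
# The DE test is a transparent exact negative-binomial test: with only two
# replicates per condition a conditional exact test on the pooled group sums
# is the defensible choice, and keeping it in-package makes every modelling
# assumption visible. Counts in each condition are library-size adjusted,
# summed, and the water-stress sum is tested against the well-watered sum
# conditional on their total, both group sums NB with a common
# method-of-moments dispersion (floored at 0.01). Two-sided p by the
# probability method (sum of conditional outcome probabilities no larger
# than the observed one).

#' Exact negative-binomial test for one gene
#'
#' @param counts_ww,counts_ws Nonnegative integer replicate counts under
#'   well-watered and water-stressed conditions (>= 2 replicates each).
#' @param norm_factors Named or ordered library-size factors for
#'   `c(counts_ww, counts_ws)` (default all 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @return list with `log2fc` (normalized WS/WW means, pseudo-count 0.5) and
#'   `p`. An all-zero gene returns `log2fc = 0`, `p = 1`.
#' @export
test_de <- function(counts_ww, counts_ws,
                    norm_factors = rep(1, length(counts_ww) + length(counts_ws)),
                    dispersion = 0.1) {
  if (length(counts_ww) < 2L || length(counts_ws) < 2L)
    stopf("need >= 2 replicates per condition")
  if (any(c(counts_ww, counts_ws) < 0)) stopf("counts must be nonnegative")
  nf <- rep(norm_factors, length.out = length(counts_ww) + length(counts_ws))
  ww <- counts_ww / nf[seq_along(counts_ww)]
  ws <- counts_ws / nf[length(counts_ww) + seq_along(counts_ws)]
  r1 <- length(ww); r2 <- length(ws)
  lfc <- log2((mean(ws) + 0.5) / (mean(ww) + 0.5))
  A <- round(sum(ww)); B <- round(sum(ws))
  if (A + B == 0) return(list(log2fc = 0, p = 1))
  p <- nb_exact_p(A, B, r1, r2, max(dispersion, 1e-8))
  list(log2fc = lfc, p = p)
}

# Conditional two-sided exact NB p-value for group sums A (r1 reps) and B
# (r2 reps) given total N = A + B. Sum of r iid NB(mu, phi) is
# NB(r * mu, phi / r) exactly, so the group sums are NB with size r / phi.
nb_exact_p <- function(A, B, r1, r2, phi) {
  N <- A + B
  m <- N * r1 / (r1 + r2)
  x <- 0:N
  la <- dnbinom(x, size = r1 / phi, mu = m, log = TRUE)
  lb <- dnbinom(N - x, size = r2 / phi, mu = N - m, log = TRUE)
  lj <- la + lb
  lj <- lj - max(lj)
  q <- exp(lj); q <- q / sum(q)
  obs <- q[A + 1L]
  min(1, sum(q[q <= obs * (1 + 1e-8)]))
}

#' Classify differential-expression status
#'
#' A gene is `up` when `padj < 0.05` and `log2fc >= 1`, `down` when
#' `padj < 0.05` and `log2fc <= -1`, otherwise `equal`.
#'
#' @param log2fc,padj Numeric vectors (finite).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_min Absolute fold-change gate on the log2 scale (default 1).
#' @return Character vector in `{up, down, equal}`.
#' @export
classify_status <- function(log2fc, padj, alpha = 0.05, lfc_min = 1) {
  stopifnot(all(is.finite(log2fc)), all(is.finite(padj)))
  ifelse(padj < alpha & log2fc >= lfc_min, "up",
         ifelse(padj < alpha & log2fc <= -lfc_min, "down", "equal"))
}

#' Per-line differential expression over a count matrix
#'
#' Runs the exact NB test gene-by-gene for each line (WS vs WW), with a
#' single across-gene method-of-moments dispersion (floored at
#' `dispersion_floor`) and Benjamini-Hochberg adjustment per line.
#'
#' @param counts Gene x sample integer matrix.
#' @param metadata A [sample_metadata()] data.frame.
#' @param lines Lines to test (default all).
#' @param norm_factors Per-sample size factors named by sample (default 1).
#' @param dispersion_floor Lower bound for the common dispersion.
#' @return data.frame with `gene_id`, `line_id`, `log2fc`, `p`, `padj`,
#'   `status`.
#' @export
run_de <- function(counts, metadata, lines = unique(metadata$line_id),
                   norm_factors = NULL, dispersion_floor = 0.01) {
  nf <- norm_factors %||% setNames(rep(1, nrow(metadata)), metadata$sample_id)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    L <- lines[li]
    s_ww <- metadata$sample_id[metadata$line_id == L & metadata$condition == "WW"]
    s_ws <- metadata$sample_id[metadata$line_id == L & metadata$condition == "WS"]
    if (length(s_ww) < 2L || length(s_ws) < 2L)
      stopf("line %s lacks 2 replicates per condition", L)
    ww <- sweep(counts[, s_ww, drop = FALSE], 2, nf[s_ww], `/`)
    ws <- sweep(counts[, s_ws, drop = FALSE], 2, nf[s_ws], `/`)
    phi <- estimate_dispersion_mom(cbind(ww, ws), c(ncol(ww), ncol(ws)),
                                   floor = dispersion_floor)
    A <- round(rowSums(ww)); B <- round(rowSums(ws))
    lfc <- log2((rowMeans(ws) + 0.5) / (rowMeans(ww) + 0.5))
    p <- vapply(seq_len(nrow(counts)), function(i) {
      if (A[i] + B[i] == 0) return(1)
      nb_exact_p(A[i], B[i], ncol(ww), ncol(ws), phi)
    }, numeric(1))
    lfc[A + B == 0] <- 0
    padj <- p.adjust(p, method = "BH")
    out[[li]] <- data.frame(gene_id = rownames(counts), line_id = L,
                            log2fc = lfc, p = p, padj = padj,
                            status = classify_status(lfc, padj),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Across-gene method-of-moments dispersion: median of per-gene
# (pooled within-group variance - mean) / mean^2, floored.
estimate_dispersion_mom <- function(mat, group_sizes, floor = 0.01) {
  r1 <- group_sizes[1]
  g1 <- mat[, seq_len(r1), drop = FALSE]
  g2 <- mat[, r1 + seq_len(group_sizes[2]), drop = FALSE]
  m1 <- rowMeans(g1); v1 <- apply(g1, 1, var)
  m2 <- rowMeans(g2); v2 <- apply(g2, 1, var)
  num <- (v1 - m1) + (v2 - m2)
  den <- m1^2 + m2^2
  ok <- den > 0 & is.finite(num)
  if (!any(ok)) return(floor)
  max(floor, median(num[ok] / den[ok]))
}

## ---- Shannon entropy -------------------------------------------------------

#' Shannon entropy of per-sample relative expression
#'
#' H = -sum P(x) log2 P(x) with P(x) the gene's relative expression in each
#' sample and 0 * log2(0) = 0. H is 0 for a gene expressed in one sample
#' and log2(N) for uniform expression; low H means specific expression.
#'
#' @param expr Nonnegative gene x sample matrix (or a single gene's vector).
#' @return data.frame with `gene_id`, `H` (bits) and `n_samples`; all-zero
#'   genes are excluded and listed in the `excluded` attribute rather than
#'   being assigned H = 0.
#' @export
shannon_entropy <- function(expr) {
  if (is.vector(expr)) expr <- matrix(expr, nrow = 1, dimnames = list("gene", NULL))
  if (any(expr < 0)) stopf("expression must be nonnegative")
  tot <- rowSums(expr)
  excluded <- rownames(expr)[tot == 0]
  keep <- tot > 0
  P <- expr[keep, , drop = FALSE] / tot[keep]
  H <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  out <- data.frame(gene_id = rownames(expr)[keep], H = H,
                    n_samples = ncol(expr), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

## ---- specific expression ---------------------------------------------------

#' Call group-specific expression
#'
#' A gene is specific to group G when it is expressed (abundance >=
#' `threshold`) in at least one sample of G and in zero samples of the
#' complement group (`rule = "any"`, the strictest reading); with
#' `rule = "all"` it must additionally be expressed in every replicate of at
#' least one line of G.
#'
#' @param fpkm Gene x sample abundance matrix.
#' @param metadata A [sample_metadata()] data.frame.
#' @param group_by `"tolerance"` (D/S), `"condition"` (WW/WS) or
#'   `"generation"` (P/RIL).
#' @param threshold Expression threshold (default 0.1).
#' @param genes Optional gene subset; genes absent from the matrix are an
#'   error.
#' @param rule `"any"` (default) or `"all"`.
#' @return Named list of gene-id vectors, one per group level.
#' @export
call_specific <- function(fpkm, metadata,
                          group_by = c("tolerance", "condition", "generation"),
                          threshold = 0.1, genes = NULL,
                          rule = c("any", "all")) {
  group_by <- match.arg(group_by)
  rule <- match.arg(rule)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(fpkm))
    if (length(miss)) stopf("gene(s) absent from matrix: %s",
                            paste(head(miss, 5), collapse = ", "))
    fpkm <- fpkm[genes, , drop = FALSE]
  }
  m <- match(colnames(fpkm), metadata$sample_id)
  if (anyNA(m)) stopf("samples absent from metadata")
  grp <- metadata[[group_by]][m]
  lev <- unique(grp)
  if (length(lev) < 2L) stopf("both groups must be non-empty")
  expressed <- fpkm >= threshold
  out <- lapply(lev, function(g) {
    ing <- rowSums(expressed[, grp == g, drop = FALSE]) > 0
    outg <- rowSums(expressed[, grp != g, drop = FALSE]) == 0
    sel <- ing & outg
    if (rule == "all") {
      lines_g <- unique(metadata$line_id[m][grp == g])
      allrep <- rep(FALSE, nrow(fpkm))
      for (L in lines_g) {
        cols <- grp == g & metadata$line_id[m] == L
        allrep <- allrep | rowSums(expressed[, cols, drop = FALSE]) == sum(cols)
      }
      sel <- sel & allrep
    }
    rownames(fpkm)[sel]
  })
  names(out) <- lev
  out
}

## ---- contingency and proportions ------------------------------------------

#' Pearson chi-square contingency report
#'
#' Pearson chi-square without continuity correction (at genome-scale table
#' sizes Yates' correction is immaterial; enable it with `correct = TRUE`).
#' Cell percentages are reported within rows, to one decimal.
#'
#' @param tab 2 x k matrix of nonnegative counts (no all-zero margin).
#' @param correct Apply Yates' continuity correction (2 x 2 only).
#' @return Object of class `contingency_report`: `table`, `chi2`, `df`, `p`,
#'   `proportions` (row percentages) and a `warning` field set when any
#'   expected cell is below 1.
#' @export
contingency <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("all-zero margin in contingency table")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  warn <- NULL
  if (any(ht$expected < 1))
    warn <- "expected cell count < 1; chi-square approximation unreliable"
  props <- sweep(tab, 1, rowSums(tab), `/`) * 100
  structure(list(table = tab,
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 proportions = round_half_up(props, 1),
                 warning = warn),
            class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  cat(sprintf("<contingency_report> chi2 = %.3f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Percentage with the reporting precision used for Table-style summaries
#'
#' Half-up rounding; one decimal place, two decimal places below 10% (the
#' precision at which sub-10% values are reported).
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param digits Override the automatic precision.
#' @return Rounded percentage `100 * numerator / denominator`.
#' @export
proportion <- function(numerator, denominator, digits = NULL) {
  if (any(denominator <= 0)) stopf("denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator))
    stopf("need 0 <= numerator <= denominator")
  pct <- 100 * numerator / denominator
  d <- digits %||% ifelse(pct < 10, 2, 1)
  round_half_up(pct, d)
}

## ---- fold-change distributions and housekeeping ----------------------------

#' Empirical fold-change distribution per gene class
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param gene_class Character vector of the same length (e.g. `"coding"`,
#'   `"lncRNA"`, `"housekeeping"`).
#' @return Named list per class with `ecdf` (a function), `iqr` and `n`.
#' @export
fc_distribution <- function(log2fc, gene_class) {
  stopifnot(length(log2fc) == length(gene_class))
  cls <- unique(gene_class)
  out <- lapply(cls, function(cl) {
    x <- log2fc[gene_class == cl]
    if (!length(x)) stopf("class %s has no results", cl)
    list(ecdf = ecdf(x), iqr = IQR(x), median = median(x), n = length(x))
  })
  names(out) <- cls
  out
}

#' Select housekeeping genes
#'
#' Genes expressed (>= `threshold`) in 100% of samples with a coefficient of
#' variation at most `cv_max`.
#'
#' @param fpkm Gene x sample abundance matrix.
#' @param threshold Expression threshold (default 0.1).
#' @param cv_max Maximum coefficient of variation (default 0.3).
#' @return Character vector of gene ids (warning when empty).
#' @export
select_housekeeping <- function(fpkm, threshold = 0.1, cv_max = 0.3) {
  everywhere <- rowSums(fpkm >= threshold) == ncol(fpkm)
  mu <- rowMeans(fpkm)
  cv <- apply(fpkm, 1, sd) / ifelse(mu > 0, mu, NA)
  sel <- everywhere & !is.na(cv) & cv <= cv_max
  if (!any(sel)) warnf("no housekeeping genes satisfy the criteria")
  rownames(fpkm)[sel]
}
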