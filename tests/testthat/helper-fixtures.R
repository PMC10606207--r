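# Fixtures built in code: tiny GTF/BED/bedGraph writers and small
# constructors shared across the suite. All deliverable fixtures are
# generated at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(withr)
})

write_toy_gtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start, end, strand, gene, tx = NA) {
  attrs <- sprintf('gene_id "%s";', gene)
  if (!is.na(tx)) attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# 2-gene toy: a 3-exon coding gene and a 1-exon lncRNA
toy_gtf_lines <- function() {
  c(gtf_line("chr1", "exon", 100, 200, "+", "g1", "g1_T1"),
    gtf_line("chr1", "exon", 300, 400, "+", "g1", "g1_T1"),
    gtf_line("chr1", "exon", 500, 700, "+", "g1", "g1_T1"),
    gtf_line("chr1", "exon", 5000, 5600, "-", "g2", "g2_T1"))
}

# Minimal stranded annotation from parallel vectors.
make_annotation <- function(chrom, start, end, strand, gene_id, biotype,
                            exon_starts = NULL, exon_ends = NULL) {
  genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                  strand = strand)
  genes$gene_id <- gene_id
  genes$biotype <- biotype
  tx <- data.frame(transcript_id = paste0(gene_id, "_T1"), gene_id = gene_id,
                   stringsAsFactors = FALSE)
  exl <- lapply(seq_along(gene_id), function(i) {
    if (is.null(exon_starts) || is.null(exon_starts[[i]]))
      GenomicRanges::GRanges(chrom[i], IRanges::IRanges(start[i], end[i]),
                             strand = strand[i])
    else
      GenomicRanges::GRanges(chrom[i],
                             IRanges::IRanges(exon_starts[[i]], exon_ends[[i]]),
                             strand = strand[i])
  })
  names(exl) <- tx$transcript_id
  gene_annotation(genes, tx, GenomicRanges::GRangesList(exl))
}

# Constant-score coverage track over [1, len].
flat_track <- function(value, len = 10000, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len), score = value)
  coverage_track(gr, seqlengths = stats::setNames(len, chrom))
}

# Track from an explicit per-base vector.
vector_track <- function(v, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(seq_along(v), seq_along(v)),
                               score = v)
  coverage_track(gr, seqlengths = stats::setNames(length(v), chrom))
}

# Feature-table row passing every cascade stage, with overridable fields.
lnc_feature_row <- function(transcript_id = "t1", ...) {
  row <- data.frame(transcript_id = transcript_id, gene_id = paste0(transcript_id, "_g"),
                    length_nt = 500L, noncoding_call_a = TRUE,
                    noncoding_call_b = TRUE, hit_identity = NA_real_,
                    hit_aa = NA_real_, hit_evalue = NA_real_,
                    rnc_abundance = 0.01, rna_abundance = 1,
                    stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) row[[nm]] <- ov[[nm]]
  row
}

# Two planted blocks of within-correlated genes (plus optional independent
# noise genes) for module-detection checks.
make_block_expr <- function(n1 = 40, n2 = 40, n_noise = 0, n_samp = 40,
                            r_within = 0.9, seed = 91) {
  withr::with_seed(seed, {
    f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
    lam <- sqrt(r_within)
    e1 <- t(vapply(seq_len(n1), function(i)
      lam * f1 + sqrt(1 - lam^2) * rnorm(n_samp), numeric(n_samp)))
    e2 <- t(vapply(seq_len(n2), function(i)
      lam * f2 + sqrt(1 - lam^2) * rnorm(n_samp), numeric(n_samp)))
    noise <- if (n_noise > 0)
      matrix(rnorm(n_noise * n_samp), n_noise) else NULL
    m <- rbind(e1, e2, noise)
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    colnames(m) <- sprintf("s%02d", seq_len(n_samp))
    list(expr = m, truth = c(rep("b1", n1), rep("b2", n2),
                             rep("noise", n_noise)))
  })
}

# Adjusted Rand index against a reference partition.
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  agree <- sum_comb(tab)
  pairs <- choose(n, 2)
  e <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / pairs
  m <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (m == e) return(1)
  (agree - e) / (m - e)
}

two_line_metadata <- function() {
  sample_metadata(
    sample_id = sprintf("L%d_%s_r%d", rep(1:2, each = 4),
                        rep(rep(c("WW", "WS"), each = 2), 2), rep(1:2, 4)),
    line_id = rep(c("RIL1", "RIL2"), each = 4),
    generation = "RIL",
    tolerance = rep(c("D", "S"), each = 4),
    condition = rep(rep(c("WW", "WS"), each = 2), 2),
    replicate = rep(1:2, 4))
}
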