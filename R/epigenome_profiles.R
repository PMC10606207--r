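# Metagene enrichment profiles around gene bodies (1 kb flanks by default)
# and group-level modification comparisons. Profiles are strand-aware: the
# x-axis always runs 5' -> 3', so minus-strand genes are reversed before
# binning; the gene body is length-normalized into a fixed number of bins.

#' Metagene layout
#'
#' @param upstream,downstream Flank sizes in bp (default 1000, the flanks
#'   used for the histone-modification comparisons).
#' @param n_up,n_body,n_down Bin counts (defaults 20/40/20; 50 bp flank
#'   bins).
#' @return list of class `metagene_layout`.
#' @export
metagene_layout <- function(upstream = 1000L, n_up = 20L, n_body = 40L,
                            n_down = 20L, downstream = 1000L) {
  stopifnot(n_up >= 1, n_body >= 1, n_down >= 1, upstream >= 1, downstream >= 1)
  structure(list(upstream = as.integer(upstream), n_up = as.integer(n_up),
                 n_body = as.integer(n_body), n_down = as.integer(n_down),
                 downstream = as.integer(downstream)),
            class = "metagene_layout")
}

# Fractional binning of a per-base vector into n bins; every bin is
# non-empty even when length(v) < n (bins then share bases).
bin_vector <- function(v, n) {
  L <- length(v)
  vapply(seq_len(n), function(b) {
    s <- floor((b - 1) * L / n) + 1L
    e <- max(s, ceiling(b * L / n))
    mean(v[s:e])
  }, numeric(1))
}

# Per-gene binned signal vector, oriented 5' -> 3'.
gene_profile <- function(track, chrom, gstart, gend, strand, layout) {
  lo <- gstart - layout$upstream
  hi <- gend + layout$downstream
  v <- track_values(track, chrom, lo, hi)
  up <- v[seq_len(layout$upstream)]
  body <- v[(layout$upstream + 1L):(layout$upstream + (gend - gstart + 1L))]
  down <- v[(length(v) - layout$downstream + 1L):length(v)]
  if (strand == "-") {
    tmp <- rev(up); up <- rev(down); down <- tmp; body <- rev(body)
  }
  c(bin_vector(up, layout$n_up), bin_vector(body, layout$n_body),
    bin_vector(down, layout$n_down))
}

#' Metagene profile of a coverage track over a gene set
#'
#' Flanks are binned at fixed width; the body is length-normalized into
#' `n_body` bins (genes shorter than the bin count are covered fractionally,
#' not an error); minus-strand genes are reversed so the profile reads
#' 5' -> 3'; the profile is the per-bin mean across genes.
#'
#' @param track A [coverage_track].
#' @param genes Stranded `GRanges` (metadata `gene_id`).
#' @param layout A [metagene_layout()].
#' @param mark,gene_class,condition Labels carried into the result.
#' @return Object of class `metagene_profile`: `bins` data.frame
#'   (`bin_label`, `region`, `mean_signal`) plus the layout and labels.
#' @export
metagene <- function(track, genes, layout = metagene_layout(),
                     mark = NA_character_, gene_class = NA_character_,
                     condition = NA_character_) {
  stopifnot(inherits(track, "coverage_track"), is(genes, "GRanges"),
            inherits(layout, "metagene_layout"))
  if (length(genes) == 0L) stopf("empty gene set")
  if (any(as.character(strand(genes)) == "*")) stopf("genes must be stranded")
  prof <- vapply(seq_along(genes), function(i)
    gene_profile(track, as.character(seqnames(genes)[i]), start(genes)[i],
                 end(genes)[i], as.character(strand(genes)[i]), layout),
    numeric(layout$n_up + layout$n_body + layout$n_down))
  mean_signal <- rowMeans(prof)
  region <- c(rep("upstream", layout$n_up), rep("body", layout$n_body),
              rep("downstream", layout$n_down))
  lab <- c(sprintf("up_%02d", seq_len(layout$n_up)),
           sprintf("body_%02d", seq_len(layout$n_body)),
           sprintf("down_%02d", seq_len(layout$n_down)))
  structure(list(mark = mark, gene_class = gene_class, condition = condition,
                 n_genes = length(genes),
                 bins = data.frame(bin_label = lab, region = region,
                                   mean_signal = mean_signal,
                                   stringsAsFactors = FALSE),
                 layout = layout),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %s / %s / %s over %d genes; peak bin %s (%.3f)\n",
              x$mark, x$gene_class, x$condition, x$n_genes,
              x$bins$bin_label[which.max(x$bins$mean_signal)],
              max(x$bins$mean_signal)))
  invisible(x)
}

#' Per-bin difference between two metagene profiles
#'
#' Computes `b - a` per bin (antisymmetric in its arguments) with sign
#' summaries over the TSS region (last two upstream + first two body bins)
#' and the body region. Layouts must match.
#'
#' @param a,b [metagene()] profiles with identical layouts.
#' @return list with `diff` (per-bin data.frame), `tss_mean_diff`,
#'   `body_mean_diff`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "metagene_profile"), inherits(b, "metagene_profile"))
  if (!identical(unclass(a$layout), unclass(b$layout)))
    stopf("profile layouts differ")
  d <- b$bins$mean_signal - a$bins$mean_signal
  lay <- a$layout
  tss_idx <- c(lay$n_up - 1L, lay$n_up, lay$n_up + 1L, lay$n_up + 2L)
  tss_idx <- tss_idx[tss_idx >= 1 & tss_idx <= length(d)]
  body_idx <- intersect(lay$n_up + seq_len(lay$n_body), seq_along(d))
  list(diff = data.frame(bin_label = a$bins$bin_label, diff = d,
                         stringsAsFactors = FALSE),
       tss_mean_diff = mean(d[tss_idx]),
       body_mean_diff = mean(d[body_idx]))
}

#' Mean signal of a track over a named gene region
#'
#' @param track A [coverage_track].
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param region `"body"` (gene span), `"tss"` or `"end3"` (strand-aware
#'   flank of `flank` bp around the 5'/3' terminus).
#' @param flank Half-window for terminus regions (default 500 bp).
#' @return data.frame `gene_id`, `mean_signal`.
#' @export
region_signal <- function(track, genes, region = c("body", "tss", "end3"),
                          flank = 500L) {
  region <- match.arg(region)
  stopifnot(is(genes, "GRanges"))
  val <- vapply(seq_along(genes), function(i) {
    chrom <- as.character(seqnames(genes)[i])
    minus <- as.character(strand(genes)[i]) == "-"
    if (region == "body") {
      lo <- start(genes)[i]; hi <- end(genes)[i]
    } else {
      anchor <- if ((region == "tss") != minus) start(genes)[i] else end(genes)[i]
      lo <- anchor - flank; hi <- anchor + flank
    }
    mean(track_values(track, chrom, lo, hi))
  }, numeric(1))
  data.frame(gene_id = genes$gene_id, mean_signal = val, stringsAsFactors = FALSE)
}

#' Two-sample test of region signal between gene groups
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` for the
#' pooled-variance form); both groups need at least 2 genes.
#'
#' @param signal Numeric signal values.
#' @param group Two-level grouping vector of the same length.
#' @param var_equal Use the pooled-variance t-test.
#' @return list with `means` (per group), `diff` (second minus first group),
#'   `p`.
#' @export
group_signal_test <- function(signal, group, var_equal = FALSE) {
  g <- as.character(group)
  lev <- unique(g)
  if (length(lev) != 2L) stopf("need exactly two groups")
  n <- table(factor(g, lev))
  if (any(n < 2L)) stopf("each group needs >= 2 genes")
  x <- signal[g == lev[1]]; y <- signal[g == lev[2]]
  ht <- t.test(y, x, var.equal = var_equal)
  list(means = setNames(c(mean(x), mean(y)), lev),
       diff = mean(y) - mean(x), p = ht$p.value)
}

#' Metagene profile in spliced transcript coordinates
#'
#' Concatenates exonic per-base signal in transcript order (minus-strand
#' transcripts reversed so the profile reads 5' -> 3') and bins the spliced
#' transcript into `n_bins` length-normalized bins. Used for m6A, which is
#' an RNA-level mark expected near the stop codon (3' end) of mRNAs.
#'
#' @param track A [coverage_track].
#' @param ann A [gene_annotation].
#' @param transcript_ids Transcripts to profile (default all).
#' @param n_bins Number of bins along the spliced transcript (default 40).
#' @param mark,gene_class,condition Labels carried into the result.
#' @return A `metagene_profile` (transcript space: no flank bins).
#' @export
transcript_profile_m6a <- function(track, ann, transcript_ids = NULL,
                                   n_bins = 40L, mark = "m6A",
                                   gene_class = NA_character_,
                                   condition = NA_character_) {
  stopifnot(inherits(track, "coverage_track"), inherits(ann, "gene_annotation"))
  txs <- transcript_ids %||% ann$transcripts$transcript_id
  if (!length(txs)) stopf("no transcripts to profile")
  prof <- vapply(txs, function(tx) {
    ex <- ann$exons[[tx]]
    if (is.null(ex)) stopf("unknown transcript %s", tx)
    v <- unlist(lapply(seq_along(ex), function(e)
      track_values(track, as.character(seqnames(ex)[e]), start(ex)[e], end(ex)[e])))
    if (length(v) == 0L) stopf("zero-length transcript %s", tx)
    if (as.character(strand(ex)[1]) == "-") v <- rev(v)
    bin_vector(v, n_bins)
  }, numeric(n_bins))
  mean_signal <- rowMeans(prof)
  structure(list(mark = mark, gene_class = gene_class, condition = condition,
                 n_genes = length(txs),
                 bins = data.frame(bin_label = sprintf("tx_%02d", seq_len(n_bins)),
                                   region = "transcript",
                                   mean_signal = mean_signal,
                                   stringsAsFactors = FALSE),
                 layout = metagene_layout(1L, 1L, n_bins, 1L, 1L)),
            class = "metagene_profile")
}
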