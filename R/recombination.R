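# Overlap of gene loci with RIL recombination fragments and enrichment of
# offspring-specific expression at recombination sites. Fragments are
# unstranded, so overlap ignores strand; the minimum overlap is 1 shared
# base (1-based inclusive adjacency, e.g. ...200 / 201..., is no overlap).

#' Overlap genes with recombination fragments
#'
#' @param ann A [gene_annotation] (or a `GRanges` of genes with `gene_id`
#'   and `biotype`).
#' @param fragments `GRanges` with a `line_id` metadata column (RIL lines).
#' @param min_overlap Minimum shared bases (default 1).
#' @return data.frame with `gene_id`, `biotype`, `lines` (comma-joined RIL
#'   set), `n_lines` and `multiplicity` (`single` when exactly one line has
#'   an event, `multiple` otherwise), one row per overlapping gene.
#' @export
overlap_fragments <- function(ann, fragments, min_overlap = 1L) {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  stopifnot(is(genes, "GRanges"), is(fragments, "GRanges"),
            !is.null(fragments$line_id))
  hits <- findOverlaps(genes, fragments, minoverlap = min_overlap,
                       ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(0), biotype = character(0),
                      lines = character(0), n_lines = integer(0),
                      multiplicity = character(0), stringsAsFactors = FALSE))
  df <- data.frame(gene_id = genes$gene_id[queryHits(hits)],
                   biotype = genes$biotype[queryHits(hits)],
                   line_id = fragments$line_id[subjectHits(hits)],
                   stringsAsFactors = FALSE)
  sp <- split(df$line_id, df$gene_id)
  lines <- vapply(sp, function(v) paste(sort(unique(v)), collapse = ","), character(1))
  n_lines <- vapply(sp, function(v) length(unique(v)), integer(1))
  bt <- df$biotype[!duplicated(df$gene_id)]
  names(bt) <- df$gene_id[!duplicated(df$gene_id)]
  out <- data.frame(gene_id = names(sp), biotype = unname(bt[names(sp)]),
                    lines = unname(lines), n_lines = unname(n_lines),
                    multiplicity = ifelse(n_lines == 1L, "single", "multiple"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enrichment of offspring-specific expression at recombination sites
#'
#' Among genes overlapping a recombination fragment, compares the
#' proportion that is offspring (RIL)-specifically expressed between
#' lncRNA and coding genes with a Pearson chi-square test. Both
#' denominators discussed for this contrast are reported: per
#' biotype-of-overlapping-genes (specific / overlapping) and per
#' specific-genes (overlapping & specific / all specific).
#'
#' @param overlaps Output of [overlap_fragments()].
#' @param specific_sets Named list from [call_specific()] with a `RIL`
#'   component (generation grouping).
#' @param all_genes Optional data.frame `gene_id`/`biotype` for the
#'   per-specific-genes denominator.
#' @return list with `proportions` (per biotype, % of overlapping genes that
#'   are RIL-specific), `report` (a [contingency()] result),
#'   `per_specific_proportions` when `all_genes` is given, and
#'   `underpowered` flag for single-gene inputs.
#' @export
recomb_enrichment <- function(overlaps, specific_sets, all_genes = NULL) {
  if (nrow(overlaps) == 0L) stopf("empty overlap set")
  if (is.null(specific_sets$RIL))
    stopf("specific_sets must come from generation (P/RIL) grouping")
  ril_spec <- specific_sets$RIL
  bts <- c("lncRNA", "coding")
  cnt <- vapply(bts, function(b) {
    g <- overlaps$gene_id[overlaps$biotype %in%
                            (if (b == "lncRNA") c("lncRNA", "lncRNA_candidate") else b)]
    c(spec = sum(g %in% ril_spec), tot = length(g))
  }, numeric(2))
  props <- setNames(vapply(bts, function(b)
    if (cnt["tot", b] > 0) 100 * cnt["spec", b] / cnt["tot", b] else NA_real_, numeric(1)), bts)
  tab <- rbind(spec = cnt["spec", ], non_spec = cnt["tot", ] - cnt["spec", ])
  underpowered <- any(cnt["tot", ] <= 1)
  report <- if (all(colSums(tab) > 0) && sum(tab) > 0 && all(rowSums(tab) > 0))
    contingency(t(tab)) else NULL
  out <- list(counts = cnt, proportions = props, report = report,
              underpowered = underpowered)
  if (!is.null(all_genes)) {
    out$per_specific_proportions <- vapply(bts, function(b) {
      gb <- all_genes$gene_id[all_genes$biotype %in%
                                (if (b == "lncRNA") c("lncRNA", "lncRNA_candidate") else b)]
      spec_b <- intersect(ril_spec, gb)
      if (!length(spec_b)) return(NA_real_)
      100 * sum(spec_b %in% overlaps$gene_id) / length(spec_b)
    }, numeric(1))
  }
  out
}
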