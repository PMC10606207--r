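# The lncRNA identification cascade and strand-aware positional
# classification. Stage order is fixed: coding-potential consensus ->
# protein-alignment filter -> translation (RNC abundance) filter ->
# length/abundance filter. A transcript is eliminated at the first stage it
# fails, so per-stage survivor counts are monotone non-increasing.

CASCADE_STAGES <- c("noncoding_consensus", "no_protein_hit", "not_translated",
                    "length_and_abundance")

#' Evaluate one cascade stage for a transcript feature table
#'
#' Stage predicates (a transcript passes a stage when the predicate is TRUE):
#' * `noncoding_consensus`: both coding-potential predictors call noncoding
#'   (intersection; switch to a union rule with `consensus = "either"`).
#' * `no_protein_hit`: the best protein hit does NOT satisfy all of
#'   identity >= 65%, aligned length > 30 aa and E-value <= 1e-9
#'   (a transcript without any hit passes).
#' * `not_translated`: RNC-seq abundance <= 0.1 (transcripts translated
#'   above 0.1 are eliminated).
#' * `length_and_abundance`: length strictly > 200 nt and RNA-seq abundance
#'   strictly > 0.1.
#'
#' @param features data.frame with columns `transcript_id`, `length_nt`,
#'   `noncoding_call_a`, `noncoding_call_b`, `hit_identity`, `hit_aa`,
#'   `hit_evalue`, `rnc_abundance`, `rna_abundance`.
#' @param stage One of `"noncoding_consensus"`, `"no_protein_hit"`,
#'   `"not_translated"`, `"length_and_abundance"`.
#' @param thresholds Named list overriding the default cutoffs
#'   (`hit_identity = 65`, `hit_aa = 30`, `hit_evalue = 1e-9`,
#'   `rnc_max = 0.1`, `min_length = 200`, `min_abundance = 0.1`).
#' @param consensus `"both"` (default, conservative intersection) or
#'   `"either"` for the coding-potential consensus.
#' @return Logical vector: TRUE where the transcript passes the stage.
#' @export
passes_stage <- function(features, stage,
                         thresholds = list(), consensus = c("both", "either")) {
  consensus <- match.arg(consensus)
  th <- modifyList(list(hit_identity = 65, hit_aa = 30, hit_evalue = 1e-9,
                        rnc_max = 0.1, min_length = 200, min_abundance = 0.1),
                   thresholds)
  if (!stage %in% CASCADE_STAGES)
    stopf("unknown cascade stage '%s'", stage)
  switch(stage,
    noncoding_consensus = {
      if (consensus == "both") features$noncoding_call_a & features$noncoding_call_b
      else features$noncoding_call_a | features$noncoding_call_b
    },
    no_protein_hit = {
      hit <- !is.na(features$hit_evalue) &
        features$hit_identity >= th$hit_identity &
        features$hit_aa > th$hit_aa &
        features$hit_evalue <= th$hit_evalue
      !hit
    },
    not_translated = features$rnc_abundance <= th$rnc_max,
    length_and_abundance =
      features$length_nt > th$min_length &
      features$rna_abundance > th$min_abundance)
}

#' Run the full lncRNA identification cascade
#'
#' Applies the four stages in fixed order; a transcript's
#' `stage_of_elimination` is the first stage it fails (or `"retained"`).
#'
#' @inheritParams passes_stage
#' @return Object of class `cascade_result` with `retained` (transcript
#'   ids), `per_stage_counts` (data.frame stage/surviving) and
#'   `stage_of_elimination` (named character vector).
#' @export
run_cascade <- function(features, thresholds = list(),
                        consensus = c("both", "either")) {
  consensus <- match.arg(consensus)
  if (nrow(features) == 0L) stopf("empty feature table")
  if (anyDuplicated(features$transcript_id))
    stopf("duplicate transcript_id: %s",
          features$transcript_id[duplicated(features$transcript_id)][1])
  elim <- setNames(rep("retained", nrow(features)), features$transcript_id)
  alive <- rep(TRUE, nrow(features))
  counts <- data.frame(stage = c("input", CASCADE_STAGES),
                       surviving = NA_integer_, stringsAsFactors = FALSE)
  counts$surviving[1] <- nrow(features)
  for (s in seq_along(CASCADE_STAGES)) {
    st <- CASCADE_STAGES[s]
    ok <- passes_stage(features, st, thresholds, consensus)
    died <- alive & !ok
    elim[features$transcript_id[died]] <- st
    alive <- alive & ok
    counts$surviving[s + 1L] <- sum(alive)
  }
  structure(list(retained = features$transcript_id[alive],
                 per_stage_counts = counts,
                 stage_of_elimination = elim),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  for (i in seq_len(nrow(x$per_stage_counts)))
    cat(sprintf("  %-22s %d\n", x$per_stage_counts$stage[i],
                x$per_stage_counts$surviving[i]))
  invisible(x)
}

## ---- positional classification --------------------------------------------

# TSS of each gene (strand-aware).
tss_of <- function(gr) ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))

#' Classify lncRNA genes by position relative to coding genes
#'
#' Strand-aware classification with precedence antisense > intronic >
#' sense_overlapping > divergent > intergenic:
#' * antisense: span overlap with a coding gene on the opposite strand;
#' * intronic: same-strand overlap with the lncRNA fully inside an intron;
#' * sense_overlapping: any other same-strand overlap;
#' * divergent: no overlap, but the lncRNA TSS lies within `upstream_window`
#'   bp upstream of a coding TSS on the opposite strand, transcribed away
#'   (head-to-head); the window is inclusive;
#' * intergenic: everything else.
#'
#' @param lnc `GRanges` of lncRNA genes (metadata `gene_id`).
#' @param ann A [gene_annotation] supplying the coding genes and their exon
#'   structure.
#' @param upstream_window Divergent TSS-to-TSS window in bp (default 2000).
#' @return data.frame with `gene_id`, `class` and `partner` (nearest coding
#'   partner for non-intergenic classes). lncRNAs on chromosomes absent from
#'   the coding annotation are classified intergenic with a warning.
#' @export
classify_position <- function(lnc, ann, upstream_window = 2000) {
  stopifnot(is(lnc, "GRanges"), inherits(ann, "gene_annotation"))
  coding <- ann$genes[ann$genes$biotype == "coding"]
  if (any(as.character(strand(lnc)) == "*") ||
      any(as.character(strand(coding)) == "*"))
    stopf("all strands must be known for positional classification")
  miss <- setdiff(as.character(unique(seqnames(lnc))),
                  as.character(unique(seqnames(coding))))
  if (length(miss))
    warnf("chromosome(s) %s absent from coding annotation; lncRNAs there are intergenic",
          paste(miss, collapse = ", "))
  cls <- rep("intergenic", length(lnc))
  partner <- rep(NA_character_, length(lnc))
  hits <- findOverlaps(lnc, coding, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  opp <- as.character(strand(lnc))[qh] != as.character(strand(coding))[sh]
  tx_of_gene <- split(ann$transcripts$transcript_id, ann$transcripts$gene_id)

  pick_partner <- function(cands, l) {
    if (length(cands) == 1L) return(cands)
    ov <- pmin(end(coding)[cands], end(l)) - pmax(start(coding)[cands], start(l))
    cands[which.max(ov)]
  }
  for (i in unique(qh)) {
    here <- which(qh == i)
    # antisense first
    anti <- here[opp[here]]
    if (length(anti)) {
      cls[i] <- "antisense"
      partner[i] <- coding$gene_id[pick_partner(sh[anti], lnc[i])]
      next
    }
    same <- sh[here[!opp[here]]]
    # intronic: fully inside an intron of some transcript of a same-strand partner
    intr <- FALSE
    for (cg in same) {
      for (tx in tx_of_gene[[coding$gene_id[cg]]]) {
        ex <- ann$exons[[tx]]
        if (length(ex) < 2L) next
        introns <- IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1L] - 1L)
        if (any(start(lnc)[i] >= start(introns) & end(lnc)[i] <= end(introns))) {
          intr <- TRUE; partner[i] <- coding$gene_id[cg]; break
        }
      }
      if (intr) break
    }
    cls[i] <- if (intr) "intronic" else "sense_overlapping"
    if (!intr) partner[i] <- coding$gene_id[pick_partner(same, lnc[i])]
  }
  # divergent among remaining non-overlapping lncRNAs
  no_ov <- setdiff(seq_along(lnc), unique(qh))
  if (length(no_ov)) {
    ct <- tss_of(coding)
    for (i in no_ov) {
      chrom <- as.character(seqnames(lnc)[i])
      ls <- as.character(strand(lnc)[i])
      lt <- if (ls == "-") end(lnc)[i] else start(lnc)[i]
      cand <- which(as.character(seqnames(coding)) == chrom &
                    as.character(strand(coding)) != ls)
      if (!length(cand)) next
      # head-to-head: lnc TSS within the window upstream of the coding TSS,
      # transcribed away from the coding gene
      up <- if (ls == "-") {
        # coding on +, its upstream is [TSS-w, TSS-1]; lnc TSS = end(lnc)
        ok <- ct[cand] - lt
        ok >= 1 & ok <= upstream_window
      } else {
        ok <- lt - ct[cand]
        ok >= 1 & ok <= upstream_window
      }
      if (any(up)) {
        cc <- cand[up]
        d <- abs(ct[cc] - lt)
        cls[i] <- "divergent"
        partner[i] <- coding$gene_id[cc[which.min(d)]]
      }
    }
  }
  data.frame(gene_id = lnc$gene_id, class = cls, partner = partner,
             stringsAsFactors = FALSE)
}

## ---- expressed counts and line-specific sets -------------------------------

#' Count expressed genes per sample and line-specific genes
#'
#' A gene is counted as expressed in a sample when its abundance meets the
#' threshold (`FPKM >= 0.1` by default; set `cmp = "gt"` for a strict
#' cutoff). A gene is specifically expressed in line L when it is expressed
#' in at least one sample of L and in no sample of any other line.
#'
#' @param fpkm Gene x sample abundance matrix (nonnegative).
#' @param metadata A [sample_metadata()] data.frame covering the samples.
#' @param threshold Expression threshold (default 0.1).
#' @param cmp `"ge"` (inclusive, default) or `"gt"`.
#' @return list with `per_sample` (named counts) and `line_specific` (named
#'   list of gene-id vectors per line).
#' @export
count_expressed <- function(fpkm, metadata, threshold = 0.1,
                            cmp = c("ge", "gt")) {
  cmp <- match.arg(cmp)
  if (any(fpkm < 0)) stopf("expression matrix must be nonnegative")
  expressed <- if (cmp == "ge") fpkm >= threshold else fpkm > threshold
  per_sample <- colSums(expressed)
  lines <- unique(metadata$line_id)
  m <- match(colnames(fpkm), metadata$sample_id)
  if (anyNA(m)) stopf("samples absent from metadata: %s",
                      paste(colnames(fpkm)[is.na(m)], collapse = ", "))
  line_of <- metadata$line_id[m]
  in_line <- vapply(lines, function(L)
    rowSums(expressed[, line_of == L, drop = FALSE]) > 0, logical(nrow(fpkm)))
  specific <- lapply(seq_along(lines), function(j) {
    others <- rowSums(in_line[, -j, drop = FALSE]) == 0
    rownames(fpkm)[in_line[, j] & others]
  })
  names(specific) <- lines
  list(per_sample = per_sample, line_specific = specific)
}
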