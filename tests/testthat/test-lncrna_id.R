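test_that("cascade stage predicates apply the published thresholds", {
  # all three alignment conditions met -> protein hit -> eliminated
  hit <- lnc_feature_row("t1", hit_identity = 70, hit_aa = 40, hit_evalue = 1e-12)
  expect_false(passes_stage(hit, "no_protein_hit"))
  # one condition failing (E-value too large) -> retained
  weak <- lnc_feature_row("t2", hit_identity = 70, hit_aa = 40, hit_evalue = 1e-8)
  expect_true(passes_stage(weak, "no_protein_hit"))
  # boundary cases of the three conditions
  expect_false(passes_stage(
    lnc_feature_row("t3", hit_identity = 65, hit_aa = 31, hit_evalue = 1e-9),
    "no_protein_hit"))  # all at the inclusive side
  expect_true(passes_stage(
    lnc_feature_row("t4", hit_identity = 64.9, hit_aa = 31, hit_evalue = 1e-9),
    "no_protein_hit"))
  expect_true(passes_stage(
    lnc_feature_row("t5", hit_identity = 65, hit_aa = 30, hit_evalue = 1e-9),
    "no_protein_hit"))  # aligned length must exceed 30 aa

  # length 200 exactly fails the strict > 200 nt rule
  expect_false(passes_stage(lnc_feature_row("t6", length_nt = 200L),
                            "length_and_abundance"))
  expect_true(passes_stage(lnc_feature_row("t7", length_nt = 201L),
                           "length_and_abundance"))

  # translation filter: RNC abundance above 0.1 eliminates
  expect_true(passes_stage(lnc_feature_row("t8", rnc_abundance = 0.1),
                           "not_translated"))
  expect_false(passes_stage(lnc_feature_row("t9", rnc_abundance = 0.10001),
                            "not_translated"))

  # consensus: both predictors must call noncoding (union by flag)
  one <- lnc_feature_row("t10", noncoding_call_b = FALSE)
  expect_false(passes_stage(one, "noncoding_consensus"))
  expect_true(passes_stage(one, "noncoding_consensus", consensus = "either"))

  expect_error(passes_stage(one, "no_such_stage"), "unknown")
})

test_that("the cascade recovers planted eliminations and rejects bad input", {
  cfg <- sim_config(seed = 10, n_coding = 30, n_lnc = 100, n_decoys_per_stage = 1)
  ann <- generate_annotation(cfg)$annotation
  fe <- generate_cascade_features(cfg, ann, include_coding = FALSE)
  res <- run_cascade(fe$features)
  expect_equal(length(res$retained), 100L)
  elim <- res$stage_of_elimination[fe$truth$transcript_id]
  expect_identical(unname(elim), fe$truth$planted_stage)
  # survivors monotone non-increasing
  expect_true(all(diff(res$per_stage_counts$surviving) <= 0))

  expect_error(run_cascade(rbind(lnc_feature_row("a"), lnc_feature_row("a"))),
               "duplicate")
  # everything translated -> empty retained set at the translation stage
  allrnc <- do.call(rbind, lapply(1:5, function(i)
    lnc_feature_row(paste0("r", i), rnc_abundance = 1.0)))
  res2 <- run_cascade(allrnc)
  expect_equal(length(res2$retained), 0L)
  expect_true(all(res2$stage_of_elimination == "not_translated"))
})

test_that("cascade is threshold-monotone and row-order invariant", {
  cfg <- sim_config(seed = 12, n_coding = 40, n_lnc = 60, n_decoys_per_stage = 4)
  ann <- generate_annotation(cfg)$annotation
  fe <- generate_cascade_features(cfg, ann)$features
  base_n <- length(run_cascade(fe)$retained)
  # tightening any threshold never increases the retained set
  grids <- list(list(rnc_max = 0.05), list(rnc_max = 0.01),
                list(min_length = 300), list(min_length = 500),
                list(min_abundance = 0.5), list(hit_evalue = 1e-6),
                list(hit_identity = 50), list(hit_aa = 20))
  prev <- base_n
  for (th in grids) {
    n <- length(run_cascade(fe, thresholds = th)$retained)
    expect_lte(n, base_n)
  }
  # nested tightening along one axis is monotone
  ns <- vapply(c(0.1, 0.08, 0.05, 0.02, 0.01, 0), function(r)
    length(run_cascade(fe, thresholds = list(rnc_max = r))$retained), numeric(1))
  expect_true(all(diff(ns) <= 0))

  perm <- sample(nrow(fe))
  res_p <- run_cascade(fe[perm, ])
  res_o <- run_cascade(fe)
  expect_setequal(res_p$retained, res_o$retained)
  expect_identical(res_p$stage_of_elimination[order(names(res_p$stage_of_elimination))],
                   res_o$stage_of_elimination[order(names(res_o$stage_of_elimination))])
})

test_that("positional classes follow the strand-aware definitions", {
  # coding gene chr1:10000-13000 (+) with two exons; various lncRNAs around it
  ann <- make_annotation(
    chrom = rep("chr1", 2), start = c(10000, 50000), end = c(13000, 52000),
    strand = c("+", "+"), gene_id = c("cod1", "cod2"),
    biotype = c("coding", "coding"),
    exon_starts = list(c(10000, 12000), 50000),
    exon_ends = list(c(10800, 13000), 52000))

  lnc <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(10100, 10900, 9500, 8200, 30000, 12500),
                     end = c(10500, 11800, 10400, 8500, 30400, 12900)),
    strand = c("-", "+", "+", "-", "+", "-"))
  lnc$gene_id <- paste0("l", 1:6)
  cls <- classify_position(lnc, ann)
  expect_equal(cls$class,
               c("antisense",          # opposite strand, overlapping an exon
                 "intronic",           # same strand, fully inside the intron
                 "sense_overlapping",  # same strand, spans exon boundary
                 "divergent",          # TSS (end, - strand) 1500 bp upstream of cod1 TSS
                 "intergenic",         # far from everything
                 "antisense"))         # opposite strand inside the gene span
  expect_equal(cls$partner[1], "cod1")
  expect_equal(cls$partner[4], "cod1")
  expect_true(is.na(cls$partner[5]))

  # window boundary: TSS exactly 2000 bp upstream is divergent (inclusive)
  lnc2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7500, 8000),
                                 strand = "-")
  lnc2$gene_id <- "lx"
  expect_equal(classify_position(lnc2, ann)$class, "divergent")
  lnc3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7400, 7999),
                                 strand = "-")
  lnc3$gene_id <- "ly"
  expect_equal(classify_position(lnc3, ann)$class, "intergenic")

  # chromosome absent from the coding annotation -> intergenic with warning
  lnc4 <- GenomicRanges::GRanges("chr9", IRanges::IRanges(100, 400), strand = "+")
  lnc4$gene_id <- "lz"
  w <- capture_warnings(cls4 <- classify_position(lnc4, ann))
  expect_true(any(grepl("absent", w)))
  expect_equal(cls4$class, "intergenic")
})

test_that("classifier recovers planted labels exactly and partitions the set", {
  for (sd in c(21, 22)) {
    cfg <- sim_config(seed = sd, n_coding = 80, n_lnc = 50)
    ag <- generate_annotation(cfg)
    lnc <- ag$annotation$genes[ag$annotation$genes$biotype != "coding"]
    cls <- classify_position(lnc, ag$annotation)
    expect_equal(nrow(cls), length(lnc))          # exactly one class each
    m <- merge(cls, ag$truth, by = "gene_id")
    expect_identical(m$class.x, m$class.y)
  }
})

test_that("classification is invariant under genome mirroring", {
  cfg <- sim_config(seed = 23, n_coding = 60, n_lnc = 40)
  ag <- generate_annotation(cfg)
  ann <- ag$annotation
  L <- max(end(ann$genes)) + 10000L
  mirror_gr <- function(gr) {
    out <- GenomicRanges::GRanges(
      seqnames(gr), IRanges::IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
      strand = ifelse(as.character(strand(gr)) == "+", "-", "+"))
    mcols(out) <- mcols(gr)
    out
  }
  genes_m <- mirror_gr(ann$genes)
  exl <- lapply(ann$transcripts$transcript_id, function(tx) sort(mirror_gr(ann$exons[[tx]])))
  names(exl) <- ann$transcripts$transcript_id
  ann_m <- gene_annotation(genes_m, ann$transcripts, GenomicRanges::GRangesList(exl))
  cls <- classify_position(ann$genes[ann$genes$biotype != "coding"], ann)
  cls_m <- classify_position(ann_m$genes[ann_m$genes$biotype != "coding"], ann_m)
  expect_identical(cls$class[order(cls$gene_id)], cls_m$class[order(cls_m$gene_id)])
})

test_that("expressed-gene counting uses the inclusive threshold and line specificity", {
  md <- two_line_metadata()
  f <- matrix(0, 3, 8, dimnames = list(paste0("g", 1:3), md$sample_id))
  f["g1", ] <- 5                      # everywhere
  f["g2", "L2_WS_r1"] <- 3            # only in RIL2, one WS replicate
  f["g3", "L1_WW_r1"] <- 0.1          # exactly at threshold
  res <- count_expressed(f, md, threshold = 0.1)
  expect_equal(unname(res$per_sample[["L1_WW_r1"]]), 2L)  # g1 + g3 (inclusive)
  expect_equal(res$line_specific$RIL2, "g2")
  expect_equal(res$line_specific$RIL1, "g3")

  zero <- matrix(0, 2, 8, dimnames = list(c("a", "b"), md$sample_id))
  rz <- count_expressed(zero, md)
  expect_true(all(rz$per_sample == 0))
  expect_true(all(lengths(rz$line_specific) == 0))
})
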