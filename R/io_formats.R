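# Readers/writers for the external formats the pipeline touches, with strict
# validation. Internal convention everywhere: 1-based, inclusive coordinates
# (GTF style); BED input is converted at the boundary by rtracklayer. Strand
# is mandatory: positional classification is strand-defined, so "." strand is
# a hard error, never a default.

## ---- gene annotation -------------------------------------------------------

#' Construct a validated gene annotation
#'
#' Container for a stranded gene/transcript/exon annotation. Genes carry a
#' biotype (`coding`, `lncRNA_candidate` or `lncRNA`); exons are grouped per
#' transcript and must be sorted, non-overlapping and contained in the gene
#' span.
#'
#' @param genes `GRanges` with metadata columns `gene_id` and `biotype`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons `GRangesList` named by `transcript_id`.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, transcripts, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"),
            is.data.frame(transcripts))
  if (is.null(genes$gene_id) || is.null(genes$biotype))
    stopf("`genes` must carry gene_id and biotype metadata columns")
  if (anyDuplicated(genes$gene_id))
    stopf("duplicated gene_id: %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  bad_bt <- setdiff(unique(genes$biotype), c("coding", "lncRNA_candidate", "lncRNA"))
  if (length(bad_bt)) stopf("unknown biotype: %s", paste(bad_bt, collapse = ", "))
  if (any(as.character(strand(genes)) == "*"))
    stopf("strand is mandatory; gene(s) without strand: %s",
          paste(head(genes$gene_id[as.character(strand(genes)) == "*"], 5), collapse = ", "))
  if (!all(transcripts$transcript_id %in% names(exons)))
    stopf("transcripts without exons: %s",
          paste(head(setdiff(transcripts$transcript_id, names(exons)), 5), collapse = ", "))
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stopf("transcript references unknown gene_id")
  # per-transcript exon structure
  gene_by_id <- setNames(seq_along(genes), genes$gene_id)
  for (i in seq_len(nrow(transcripts))) {
    ex <- exons[[transcripts$transcript_id[i]]]
    if (length(ex) == 0L) stopf("transcript %s has no exons", transcripts$transcript_id[i])
    if (is.unsorted(start(ex))) stopf("exons of %s not sorted", transcripts$transcript_id[i])
    if (length(ex) > 1L && any(start(ex)[-1] <= end(ex)[-length(ex)]))
      stopf("overlapping exons in transcript %s", transcripts$transcript_id[i])
    g <- genes[gene_by_id[[transcripts$gene_id[i]]]]
    if (min(start(ex)) < start(g) || max(end(ex)) > end(g))
      stopf("exons of %s outside gene span of %s",
            transcripts$transcript_id[i], transcripts$gene_id[i])
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes (%s), %d transcripts\n",
              length(x$genes),
              paste(sprintf("%s: %d", names(table(x$genes$biotype)),
                            as.integer(table(x$genes$biotype))), collapse = ", "),
              nrow(x$transcripts)))
  invisible(x)
}

#' Number of exons per transcript
#' @param ann A `gene_annotation`.
#' @return Named integer vector, one entry per transcript.
#' @export
exon_counts <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  setNames(lengths(ann$exons)[ann$transcripts$transcript_id],
           ann$transcripts$transcript_id)
}

#' Gene lengths (end - start + 1)
#' @param ann A `gene_annotation`.
#' @return Named integer vector per gene.
#' @export
gene_lengths <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  setNames(width(ann$genes), ann$genes$gene_id)
}

# Spliced transcript length = sum of exon widths.
transcript_lengths <- function(ann) {
  setNames(vapply(ann$transcripts$transcript_id,
                  function(tx) sum(width(ann$exons[[tx]])), integer(1)),
           ann$transcripts$transcript_id)
}

#' Read a GTF annotation
#'
#' Parses an Ensembl-dialect GTF (via rtracklayer) into a validated
#' [gene_annotation]. Malformed coordinates (end < start) and missing strands
#' are hard errors naming the offending line.
#'
#' @param path Path to a GTF file.
#' @return A `gene_annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # cheap pre-scan so coordinate errors name their line
  ln <- readLines(path)
  body <- which(!startsWith(ln, "#") & nzchar(ln))
  fields <- strsplit(ln[body], "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 9) stopf("line %d: fewer than 9 GTF fields", body[k])
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) stopf("line %d: non-numeric coordinates", body[k])
    if (e < s) stopf("line %d: end (%s) < start (%s)", body[k], f[5], f[4])
    if (!f[7] %in% c("+", "-")) stopf("line %d: missing or invalid strand '%s'", body[k], f[7])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  build_annotation_from_gtf(gr)
}

build_annotation_from_gtf <- function(gr) {
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stopf("GTF contains no exon records")
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stopf("exon records must carry transcript_id")
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stopf("exon records must carry gene_id")
  ex <- sort(ex)
  exl <- split(granges(ex), ex$transcript_id)
  tx2gene <- unique(data.frame(transcript_id = ex$transcript_id,
                               gene_id = ex$gene_id,
                               stringsAsFactors = FALSE))
  if (anyDuplicated(tx2gene$transcript_id))
    stopf("transcript assigned to multiple genes: %s",
          tx2gene$transcript_id[duplicated(tx2gene$transcript_id)][1])
  # gene span = union of its exons; biotype from gene records when present
  sp <- split(granges(ex), ex$gene_id)
  gspan <- unlist(range(sp))
  genes <- GRanges(seqnames(gspan), ranges(gspan), strand = strand(gspan))
  genes$gene_id <- names(gspan)
  bt <- rep("coding", length(genes))
  grec <- gr[gr$type == "gene"]
  if (length(grec) && !is.null(grec$gene_biotype)) {
    m <- match(genes$gene_id, grec$gene_id)
    bt <- ifelse(!is.na(m) & !is.na(grec$gene_biotype[m]), grec$gene_biotype[m], bt)
  }
  genes$biotype <- bt
  names(genes) <- NULL
  ord <- order(genes$gene_id)
  gene_annotation(genes[ord], tx2gene[order(tx2gene$transcript_id), , drop = FALSE], exl)
}

#' Write a gene annotation to GTF
#'
#' Emits gene, transcript and exon records in Ensembl attribute dialect;
#' round-trips with [read_annotation()].
#'
#' @param ann A `gene_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- granges(ann$genes)
  g$type <- "gene"; g$gene_id <- ann$genes$gene_id
  g$gene_biotype <- ann$genes$biotype
  g$transcript_id <- NA_character_
  exs <- lapply(seq_len(nrow(ann$transcripts)), function(i) {
    e <- ann$exons[[ann$transcripts$transcript_id[i]]]
    e$type <- "exon"
    e$gene_id <- ann$transcripts$gene_id[i]
    e$gene_biotype <- NA_character_
    e$transcript_id <- ann$transcripts$transcript_id[i]
    e
  })
  out <- c(g, do.call(c, exs))
  out$source <- "lncdrought"
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

## ---- expression matrices ---------------------------------------------------

#' Construct sample metadata
#'
#' @param sample_id,line_id Character vectors.
#' @param generation `"P"` (parent) or `"RIL"`.
#' @param tolerance `"D"` (drought-tolerant) or `"S"` (drought-sensitive).
#' @param condition `"WW"` (well-watered) or `"WS"` (water-stressed).
#' @param replicate Integer replicate index (>= 1).
#' @return A data.frame of class `sample_meta`.
#' @export
sample_metadata <- function(sample_id, line_id, generation, tolerance,
                            condition, replicate) {
  md <- data.frame(sample_id = as.character(sample_id),
                   line_id = as.character(line_id),
                   generation = as.character(generation),
                   tolerance = as.character(tolerance),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) stopf("duplicated sample_id")
  if (!all(md$generation %in% c("P", "RIL"))) stopf("generation must be P or RIL")
  if (!all(md$tolerance %in% c("D", "S"))) stopf("tolerance must be D or S")
  if (!all(md$condition %in% c("WW", "WS"))) stopf("condition must be WW or WS")
  if (any(md$replicate < 1L)) stopf("replicate must be >= 1")
  key <- paste(md$line_id, md$condition, md$replicate)
  if (anyDuplicated(key))
    stopf("duplicated (line_id, condition, replicate): %s", key[duplicated(key)][1])
  class(md) <- c("sample_meta", "data.frame")
  md
}

#' Read an expression matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample. Missing or
#' negative cells and duplicated genes are hard errors; when `metadata` is
#' supplied every matrix sample must be declared in it.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param metadata Optional [sample_metadata()] data.frame.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, metadata = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (colnames(df)[1] != "gene_id") stopf("first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stopf("duplicated gene_id row(s): %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric expression cells")
  if (anyNA(m)) stopf("missing expression cells are not allowed")
  if (any(m < 0)) stopf("negative expression values are not allowed")
  rownames(m) <- df$gene_id
  if (!is.null(metadata)) {
    extra <- setdiff(colnames(m), metadata$sample_id)
    if (length(extra))
      stopf("samples absent from metadata: %s", paste(extra, collapse = ", "))
  }
  m
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- recombination fragments (BED) ----------------------------------------

#' Read recombination fragments from BED4
#'
#' BED is half-open 0-based; rtracklayer converts to the internal 1-based
#' inclusive convention on import. Column 4 (`name`) carries the RIL line id.
#' Overlapping fragments for one line are legal and preserved.
#'
#' @param path Path to a BED4 file.
#' @return `GRanges` with metadata column `line_id` (empty for an empty file).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#") & !startsWith(ln, "track")]
  if (length(ln) == 0L) {
    gr <- GRanges(); gr$line_id <- character(0); return(gr)
  }
  fields <- strsplit(ln, "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 4) stopf("BED line %d: need 4 columns (chrom start end line_id)", k)
    s <- suppressWarnings(as.numeric(f[2]))
    if (is.na(s) || s < 0) stopf("BED line %d: negative or invalid start", k)
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- granges(gr)
  out$line_id <- gr$name
  out
}

#' Write fragments to BED4
#' @param gr `GRanges` with a `line_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  stopifnot(is(gr, "GRanges"), !is.null(gr$line_id))
  out <- granges(gr)
  names(out) <- gr$line_id
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

## ---- coverage tracks (bedGraph) -------------------------------------------

#' Construct a coverage track from scored intervals
#'
#' @param gr `GRanges` (1-based inclusive) with numeric `score`; intervals
#'   must be sorted and non-overlapping within each chromosome.
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return Object of class `coverage_track`: queryable per-base signal
#'   (absent regions read as 0).
#' @export
coverage_track <- function(gr, seqlengths = NULL) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(gr$score)) stopf("coverage intervals must carry a numeric score")
  for (chr in unique(as.character(seqnames(gr)))) {
    g <- gr[seqnames(gr) == chr]
    if (is.unsorted(start(g))) stopf("coverage intervals unsorted on %s", chr)
    if (length(g) > 1L && any(start(g)[-1] <= end(g)[-length(g)]))
      stopf("overlapping coverage intervals on %s", chr)
  }
  sl <- seqlengths %||% tapply(end(gr), as.character(seqnames(gr)), max)
  cov <- lapply(names(sl), function(chr) {
    g <- gr[seqnames(gr) == chr]
    L <- as.integer(sl[[chr]])
    if (length(g) == 0L) return(Rle(0, L))
    # intervals are sorted and non-overlapping: build the Rle run-wise,
    # interleaving zero-gaps with interval scores
    s <- start(g); e <- end(g); sc <- g$score
    lens <- as.vector(rbind(s - c(0L, e[-length(e)]) - 1L, e - s + 1L))
    vals <- as.vector(rbind(0, sc))
    if (L > e[length(e)]) { lens <- c(lens, L - e[length(e)]); vals <- c(vals, 0) }
    keep <- lens > 0L
    Rle(vals[keep], lens[keep])
  })
  names(cov) <- names(sl)
  structure(list(cov = cov, intervals = gr,
                 seqlengths = setNames(as.integer(sl), names(sl))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d interval(s) on %d chromosome(s)\n",
              length(x$intervals), length(x$cov)))
  invisible(x)
}

#' Query per-base signal from a coverage track
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions (clamped to the track).
#' @return Numeric vector of per-base values; positions outside any interval
#'   (or off the track) are 0.
#' @export
track_values <- function(track, chrom, start, end = start) {
  stopifnot(inherits(track, "coverage_track"), end >= start)
  n <- end - start + 1L
  out <- numeric(n)
  r <- track$cov[[chrom]]
  if (is.null(r)) return(out)
  L <- length(r)
  s <- max(1L, start); e <- min(L, end)
  if (s > e) return(out)
  out[(s - start + 1L):(e - start + 1L)] <- as.numeric(r[s:e])
  out
}

#' Read a bedGraph coverage track
#'
#' Requires sorted, non-overlapping intervals per chromosome (error
#' otherwise); converts 0-based half-open records to 1-based inclusive.
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Optional named chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(gr, seqlengths = seqlengths)
}

#' Write a coverage track to bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  rtracklayer::export(track$intervals, path, format = "bedGraph")
  invisible(path)
}
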