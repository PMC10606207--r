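# Seeded generator for inputs with the statistical structure the analysis
# assumes: a biparental RIL design (2 parents + RILs, WW/WS, 2 replicates),
# low lncRNA expression, an excess of drought down-regulation, TSS-peaked
# histone marks, stop-codon-proximal m6A on mRNA, recombination fragments,
# planted trait-associated SNPs and planted miRNA bridges. Every planted
# truth label is returned in a `truth` sidecar consumed only by tests.

#' Simulation configuration
#'
#' Defaults emulate the observed structure of the study design: 14 RILs plus
#' two parents, 82.3% single-exon lncRNAs, positional class proportions
#' 90.1/4.6/3.7% (intergenic/antisense/divergent), lncRNA expression lower
#' than coding, drought down-regulation excess (lncRNA down-probability
#' 0.505 vs coding 0.298), 1320 recombination fragments and a 368-line
#' association panel.
#'
#' @param seed Integer master seed; fully determines all generated data.
#' @param n_coding,n_lnc Numbers of coding and lncRNA genes.
#' @param n_ril Number of recombinant inbred lines (split evenly into
#'   drought-tolerant D and drought-sensitive S); two parents are added.
#' @param n_chrom,chrom_length Genome layout; `chrom_length = NULL` auto-sizes
#'   each chromosome to fit the genes.
#' @param frac_lnc_single_exon Proportion of single-exon lncRNAs.
#' @param class_props Named positional-class proportions for lncRNAs
#'   (intergenic, antisense, divergent, intronic, sense_overlapping).
#' @param coding_expr_meanlog,lnc_expr_meanlog,expr_sdlog Log-normal FPKM
#'   baselines; the lncRNA scale must be below the coding scale.
#' @param de_config Per-class up/down/equal probabilities under water stress.
#' @param de_lfc_range Range of planted |log2 fold change| for up/down genes.
#' @param dispersion Negative-binomial dispersion of counts.
#' @param frac_housekeeping Fraction of coding genes planted as uniformly
#'   expressed housekeeping genes (near-zero dispersion).
#' @param specific_config Per-class probabilities that a gene is specifically
#'   expressed in one group (D, S, WW, WS, P, RIL).
#' @param depth_per_fpkm Expected counts per FPKM unit at size factor 1.
#' @param line_effect_sdlog Log-normal sd of per-line expression
#'   heterogeneity (named, per gene class); larger for lncRNAs, zero for
#'   housekeeping genes.
#' @param n_fragments Number of recombination fragments.
#' @param n_snps Number of null SNPs; `sig_snp_rate_lnc` significant SNPs per
#'   kb are planted in lncRNA loci and `sig_snp_rate_lnc / snp_enrichment`
#'   per kb in coding loci.
#' @param sig_snp_rate_lnc,snp_enrichment Planted significant-SNP density in
#'   lncRNA genes (per kb) and lnc:coding enrichment factor.
#' @param n_panel Natural-population panel size for genotype-trait tests.
#' @param assoc_beta,trait_noise_sd Per-allele trait effect of planted SNPs
#'   and residual trait standard deviation.
#' @param mark_profiles Per-mark metagene shape parameters (see
#'   [default_mark_profiles()]).
#' @param track_bin,track_noise_sd Coverage-track bin width (bp) and additive
#'   Gaussian noise per bin.
#' @param n_decoys_per_stage Cascade decoys violating exactly one stage each.
#' @param n_bridges,n_distractors Planted ceRNA bridges and per-table
#'   distractor rows (distractors share no miRNA across RNA classes).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_coding = 600L, n_lnc = 150L,
                       n_ril = 14L,
                       n_chrom = 2L, chrom_length = NULL,
                       frac_lnc_single_exon = 0.823,
                       class_props = c(intergenic = 0.901, antisense = 0.046,
                                       divergent = 0.037, intronic = 0.008,
                                       sense_overlapping = 0.008),
                       coding_expr_meanlog = log(50), lnc_expr_meanlog = log(8),
                       expr_sdlog = 1,
                       de_config = list(
                         coding = c(up = 0.214, down = 0.298, equal = 0.488),
                         lnc    = c(up = 0.389, down = 0.505, equal = 0.106)),
                       de_lfc_range = c(1.5, 3),
                       dispersion = 0.1,
                       frac_housekeeping = 0.05,
                       specific_config = list(
                         lnc    = c(D = 0.047, S = 0.046, WW = 0.038, WS = 0.059,
                                    P = 0.002, RIL = 0.19),
                         coding = c(D = 0.040, S = 0.026, WW = 0.021, WS = 0.018,
                                    P = 0.005, RIL = 0.081)),
                       depth_per_fpkm = 2,
                       line_effect_sdlog = c(coding = 0.3, lnc = 0.8),
                       n_fragments = 1320L,
                       n_snps = 2000L,
                       sig_snp_rate_lnc = 0.5, snp_enrichment = 3,
                       n_panel = 368L,
                       assoc_beta = 8, trait_noise_sd = 10,
                       mark_profiles = default_mark_profiles(),
                       track_bin = 25L, track_noise_sd = 0.02,
                       n_decoys_per_stage = 5L,
                       n_bridges = 10L, n_distractors = 100L) {
  cfg <- as.list(environment())
  stopifnot(n_coding >= 2, n_lnc >= 0, n_ril >= 2, n_chrom >= 1)
  if (abs(sum(class_props) - 1) > 1e-8) stopf("class_props must sum to 1")
  if (frac_lnc_single_exon < 0 || frac_lnc_single_exon > 1)
    stopf("frac_lnc_single_exon must be in [0,1]")
  for (cl in names(de_config)) {
    p <- de_config[[cl]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("de_config$%s probabilities must be in [0,1] and sum to 1", cl)
  }
  if (lnc_expr_meanlog >= coding_expr_meanlog)
    stopf("lnc expression scale must be below the coding scale")
  for (cl in names(specific_config))
    if (sum(specific_config[[cl]]) > 1)
      stopf("specific_config$%s probabilities exceed 1", cl)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d coding + %d lncRNA genes, %d RILs + 2 parents, %d chromosome(s)\n",
              x$seed, x$n_coding, x$n_lnc, x$n_ril, x$n_chrom))
  invisible(x)
}

#' Default metagene shape parameters per modification mark
#'
#' Histone methylation/acetylation marks peak at the TSS, higher on coding
#' genes than on lncRNA genes; activating marks (H3K4me3, H3K9ac, H3K27ac)
#' shift down under water stress while H3K4me1/H3K9me3/H3K36me3 shift up;
#' DNA methylation (mC) is higher on lncRNA gene bodies; m6A peaks near the
#' mRNA 3' end (stop-codon region) and has no peak on lncRNAs.
#'
#' @return data.frame of per-mark parameters.
#' @export
default_mark_profiles <- function() {
  data.frame(
    mark       = c("H3K4me3", "H3K9ac", "H3K27ac", "H3K4me1", "H3K9me3",
                   "H3K36me3", "mC", "m6A"),
    body_coding = c(1.0, 0.8, 0.8, 1.5, 1.2, 1.5, 1.0, 1.0),
    body_lnc    = c(0.6, 0.5, 0.5, 1.2, 1.2, 0.8, 2.0, 0.5),
    tss_height_coding = c(6, 5, 4, 2, 1.5, 2, 0, 0),
    tss_height_lnc    = c(3, 2.5, 2, 1.5, 1.2, 0.5, 0, 0),
    end3_height_coding = c(0, 0, 0, 0, 0, 0, 0, 3),
    end3_height_lnc    = c(0, 0, 0, 0, 0, 0, 0, 0),
    tss_sd     = c(150, 150, 150, 200, 200, 200, 150, 100),
    ws_shift   = c(-0.5, -0.4, -0.3, 0.4, 0.3, 0.3, 0, 0.5),
    stringsAsFactors = FALSE)
}

## ---- samples ---------------------------------------------------------------

#' Generate the sample sheet for the RIL design
#'
#' Two parents (drought-tolerant and drought-sensitive) plus `n_ril` RILs
#' split into D and S classes, each under WW and WS with 2 replicates.
#'
#' @param cfg A [sim_config()].
#' @return A [sample_metadata()] data.frame.
#' @export
generate_samples <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_ril
  if (n == 14L) {
    rils <- c("RIL231", "RIL131", "RIL155", "RIL203", "RIL142", "RIL208",
              "RIL165", "RIL126", "RIL64", "RIL226", "RIL27", "RIL47",
              "RIL8", "RIL166")
    tol <- rep(c("D", "S"), each = 7)
  } else {
    rils <- sprintf("RIL%02d", seq_len(n))
    tol <- rep(c("D", "S"), length.out = n)
  }
  lines <- data.frame(line_id = c("P1_AC7643", "P2_AC7729", rils),
                      generation = c("P", "P", rep("RIL", n)),
                      tolerance = c("D", "S", tol),
                      stringsAsFactors = FALSE)
  grid <- expand.grid(replicate = 1:2, condition = c("WW", "WS"),
                      line = seq_len(nrow(lines)), stringsAsFactors = FALSE)
  sample_metadata(
    sample_id = sprintf("%s_%s_r%d", lines$line_id[grid$line], grid$condition,
                        grid$replicate),
    line_id = lines$line_id[grid$line],
    generation = lines$generation[grid$line],
    tolerance = lines$tolerance[grid$line],
    condition = as.character(grid$condition),
    replicate = grid$replicate)
}

## ---- annotation ------------------------------------------------------------

# Exon layout within a [1, L] span: n_ex exons separated by introns,
# roughly half the span exonic.
partition_exons <- function(L, n_ex) {
  if (n_ex == 1L) return(cbind(start = 1L, end = as.integer(L)))
  ew <- runif(n_ex, 0.5, 1.5); iw <- runif(n_ex - 1, 0.5, 1.5)
  ew <- pmax(20L, as.integer(round(ew / sum(ew) * 0.5 * L)))
  iw <- pmax(20L, as.integer(round(iw / sum(iw) * 0.5 * L)))
  st <- en <- integer(n_ex); pos <- 1L
  for (i in seq_len(n_ex)) {
    st[i] <- pos
    en[i] <- pos + ew[i] - 1L
    if (i < n_ex) pos <- en[i] + 1L + iw[i]
  }
  en[n_ex] <- as.integer(L)
  if (en[n_ex] <= st[n_ex]) en[n_ex] <- st[n_ex] + 20L
  cbind(start = st, end = en)
}

#' Generate a synthetic gene annotation with planted positional classes
#'
#' Coding genes are multi-exon and longer on average; lncRNA genes realize
#' all positional classes (intergenic, antisense, divergent, intronic,
#' sense-overlapping) in the configured proportions, placed so the
#' positional classifier can recover the planted labels exactly.
#'
#' @param cfg A [sim_config()].
#' @return list with `annotation` (a [gene_annotation]) and `truth`
#'   (data.frame of planted lncRNA class labels and partner genes; consumed
#'   only by tests, never by the pipeline).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "annotation"), {
    n_per <- rep(cfg$n_coding %/% cfg$n_chrom, cfg$n_chrom)
    n_per[seq_len(cfg$n_coding %% cfg$n_chrom)] <-
      n_per[seq_len(cfg$n_coding %% cfg$n_chrom)] + 1L
    slot <- 15000L
    need <- n_per * slot + 10000L
    if (is.null(cfg$chrom_length)) {
      chrom_len <- need
    } else {
      chrom_len <- rep(as.integer(cfg$chrom_length), length.out = cfg$n_chrom)
      if (any(chrom_len < need))
        stopf("infeasible placement: %d genes need >= %d bp on %s",
              n_per[which(chrom_len < need)[1]], need[which(chrom_len < need)[1]],
              paste0("chr", which(chrom_len < need)[1]))
      slot <- min((chrom_len - 10000L) %/% pmax(n_per, 1L))
      if (slot < 12000L)
        stopf("infeasible placement: per-gene slot %d bp < 12000 bp", slot)
    }
    chroms <- paste0("chr", seq_len(cfg$n_chrom))

    g_chrom <- character(0); g_start <- g_end <- integer(0); g_strand <- character(0)
    exon_list <- list(); tx_ids <- gene_ids <- character(0)
    coding_rows <- list()
    gi <- 0L
    for (ci in seq_len(cfg$n_chrom)) {
      for (k in seq_len(n_per[ci])) {
        gi <- gi + 1L
        len <- as.integer(round(rlnorm(1, log(2500), 0.4)))
        len <- max(800L, min(len, slot - 6000L))
        st <- as.integer((k - 1L) * slot + 2500L + round(runif(1, 0, 500)))
        id <- sprintf("CDG%05d", gi)
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(1:8, 1, prob = c(0.10, 0.15, 0.2, 0.2, 0.15, 0.1, 0.06, 0.04))
        ex <- partition_exons(len, n_ex)
        g_chrom <- c(g_chrom, chroms[ci]); g_start <- c(g_start, st)
        g_end <- c(g_end, st + len - 1L); g_strand <- c(g_strand, strand)
        gene_ids <- c(gene_ids, id); tx_ids <- c(tx_ids, paste0(id, "_T1"))
        exon_list[[paste0(id, "_T1")]] <-
          GRanges(chroms[ci], IRanges(st + ex[, "start"] - 1L, st + ex[, "end"] - 1L),
                  strand = strand)
        coding_rows[[gi]] <- list(chrom = chroms[ci], start = st,
                                  end = st + len - 1L, strand = strand,
                                  n_ex = n_ex, gene_id = id, exons = ex)
      }
    }
    biotype <- rep("coding", cfg$n_coding)

    # planted lncRNA classes
    cls_n <- floor(cfg$class_props * cfg$n_lnc)
    rem <- cfg$n_lnc - sum(cls_n)
    if (rem > 0) {
      ord <- order(cfg$class_props * cfg$n_lnc - cls_n, decreasing = TRUE)
      cls_n[ord[seq_len(rem)]] <- cls_n[ord[seq_len(rem)]] + 1L
    }
    classes <- rep(names(cls_n), cls_n)
    truth <- data.frame(gene_id = character(0), class = character(0),
                        partner = character(0), stringsAsFactors = FALSE)
    cod <- coding_rows
    multi_exon_hosts <- which(vapply(cod, function(r) r$n_ex >= 2, logical(1)))
    for (j in seq_along(classes)) {
      cl <- classes[j]
      id <- sprintf("XLOC_%06d", j)
      len <- as.integer(round(rlnorm(1, log(600), 0.5)))
      len <- max(250L, min(len, 2000L))
      n_ex <- if (runif(1) < cfg$frac_lnc_single_exon) 1L else sample(2:5, 1)
      # spliced length (about half the span for multi-exon genes) must stay
      # comfortably above the 200 nt cascade threshold
      if (n_ex > 1L) len <- max(len, 600L)
      partner <- NA_character_
      if (cl == "antisense") {
        h <- cod[[sample(seq_along(cod), 1)]]
        len <- min(len, h$end - h$start - 100L)
        st <- as.integer(h$start + round(runif(1, 0, h$end - h$start + 1L - len)))
        strand <- if (h$strand == "+") "-" else "+"
        chrom <- h$chrom; partner <- h$gene_id
      } else if (cl == "intronic") {
        ok <- FALSE
        for (try in seq_len(50)) {
          h <- cod[[sample(multi_exon_hosts, 1)]]
          ir <- cbind(h$exons[-nrow(h$exons), "end"] + 1L,
                      h$exons[-1L, "start"] - 1L)
          wid <- ir[, 2] - ir[, 1] + 1L
          if (max(wid) >= 300L) { ok <- TRUE; break }
        }
        if (!ok) stopf("no intron wide enough to host an intronic lncRNA")
        i <- which.max(wid)
        len <- min(len, wid[i] - 40L)
        st <- as.integer(h$start - 1L + ir[i, 1] + 20L)
        strand <- h$strand; chrom <- h$chrom; partner <- h$gene_id
      } else if (cl == "sense_overlapping") {
        h <- cod[[sample(seq_along(cod), 1)]]
        strand <- h$strand; chrom <- h$chrom; partner <- h$gene_id
        if (h$strand == "+") st <- as.integer(h$start - len + 100L)
        else st <- as.integer(h$end - 99L)
        st <- max(1L, st)
      } else if (cl == "divergent") {
        h <- cod[[sample(seq_along(cod), 1)]]
        chrom <- h$chrom; partner <- h$gene_id
        d <- as.integer(round(runif(1, 300, 1800)))
        if (h$strand == "+") {          # lnc on -, TSS upstream of host TSS
          strand <- "-"
          en <- h$start - d; st <- as.integer(en - len + 1L)
        } else {                         # lnc on +, TSS downstream of host end
          strand <- "+"
          st <- as.integer(h$end + d)
        }
        st <- max(1L, st)
      } else {                           # intergenic: centered mid-gap
        h_idx <- sample(seq_along(cod)[-length(cod)], 1)
        h <- cod[[h_idx]]; nxt <- cod[[h_idx + 1L]]
        len <- min(len, 1200L)
        mid <- if (identical(h$chrom, nxt$chrom))
          as.integer((h$end + nxt$start) %/% 2L)
        else
          as.integer(h$end + 7000L)   # last gene of its chromosome
        st <- as.integer(mid - len %/% 2L)
        strand <- sample(c("+", "-"), 1)
        chrom <- h$chrom
      }
      en <- st + len - 1L
      if (n_ex > 1L && len < 600L) n_ex <- 1L   # clamped by a host feature
      ex <- partition_exons(len, n_ex)
      g_chrom <- c(g_chrom, chrom); g_start <- c(g_start, st)
      g_end <- c(g_end, en); g_strand <- c(g_strand, strand)
      gene_ids <- c(gene_ids, id); tx_ids <- c(tx_ids, paste0(id, "_T1"))
      exon_list[[paste0(id, "_T1")]] <-
        GRanges(chrom, IRanges(st + ex[, "start"] - 1L, st + ex[, "end"] - 1L),
                strand = strand)
      biotype <- c(biotype, "lncRNA")
      truth <- rbind(truth, data.frame(gene_id = id, class = cl,
                                       partner = partner, stringsAsFactors = FALSE))
    }
    genes <- GRanges(g_chrom, IRanges(g_start, g_end), strand = g_strand,
                     seqlengths = setNames(chrom_len, chroms))
    genes$gene_id <- gene_ids
    genes$biotype <- biotype
    tx <- data.frame(transcript_id = tx_ids, gene_id = gene_ids,
                     stringsAsFactors = FALSE)
    ann <- gene_annotation(genes, tx, GRangesList(exon_list))
    list(annotation = ann, truth = truth)
  })
}

## ---- expression ------------------------------------------------------------

#' Generate counts and FPKM with planted differential expression
#'
#' Per-gene water-stress response labels (up/down/equal) are drawn from the
#' class-specific `de_config` probabilities and realized as a log2
#' fold-change of planted magnitude in every line; counts are
#' negative-binomial around FPKM-implied means with fixed per-sample size
#' factors; a housekeeping subset of coding genes is expressed uniformly
#' across all samples; group-specific genes are silenced outside their
#' group.
#'
#' @param cfg A [sim_config()].
#' @param ann A [gene_annotation].
#' @param samples A [sample_metadata()] sheet with both conditions and at
#'   least 2 replicates each (error otherwise).
#' @return list with `counts`, `fpkm` (gene x sample matrices) and `truth`
#'   (per-gene planted label, fold change, specificity, housekeeping flag).
#' @export
generate_expression <- function(cfg, ann, samples = generate_samples(cfg)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "gene_annotation"))
  tab <- table(samples$line_id, samples$condition)
  if (ncol(tab) < 2 || any(tab < 2))
    stopf("every line needs >= 2 replicates under both WW and WS")
  with_seed(derive_seed(cfg$seed, "expression"), {
    ids <- ann$genes$gene_id
    is_lnc <- ann$genes$biotype != "coding"
    n <- length(ids)
    base <- ifelse(is_lnc,
                   rlnorm(n, cfg$lnc_expr_meanlog, cfg$expr_sdlog),
                   rlnorm(n, cfg$coding_expr_meanlog, cfg$expr_sdlog))
    hk <- rep(FALSE, n)
    cod_idx <- which(!is_lnc)
    hk[sample(cod_idx, round(cfg$frac_housekeeping * length(cod_idx)))] <- TRUE

    draw_label <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)
    label <- character(n)
    label[is_lnc] <- draw_label(cfg$de_config$lnc, sum(is_lnc))
    label[!is_lnc] <- draw_label(cfg$de_config$coding, sum(!is_lnc))
    label[hk] <- "equal"
    lfc <- ifelse(label == "equal", 0,
                  runif(n, cfg$de_lfc_range[1], cfg$de_lfc_range[2]))
    lfc[label == "down"] <- -lfc[label == "down"]

    spec_group <- rep("none", n)
    for (cl in c("lnc", "coding")) {
      p <- cfg$specific_config[[if (cl == "lnc") "lnc" else "coding"]]
      idx <- which(if (cl == "lnc") is_lnc else (!is_lnc & !hk))
      pr <- c(p, none = 1 - sum(p))
      spec_group[idx] <- sample(names(pr), length(idx), replace = TRUE, prob = pr)
    }
    # specifically expressed genes must be detectably expressed in their group
    base[spec_group != "none"] <- pmax(base[spec_group != "none"], 2)

    ns <- nrow(samples)
    sf <- runif(ns, 0.85, 1.15)
    disp <- ifelse(hk, 0.002, cfg$dispersion)
    mu_fpkm <- (base %o% rep(1, ns)) * 2^(lfc %o% as.numeric(samples$condition == "WS"))
    # line-to-line heterogeneity: stronger for lncRNAs (their expression is
    # line-specific in the field's sense), absent for housekeeping genes
    lines <- unique(samples$line_id)
    lf_sd <- ifelse(hk, 0, ifelse(is_lnc, cfg$line_effect_sdlog[["lnc"]],
                                  cfg$line_effect_sdlog[["coding"]]))
    line_fac <- matrix(rlnorm(n * length(lines), 0, rep(lf_sd, length(lines))),
                       nrow = n)
    mu_fpkm <- mu_fpkm * line_fac[, match(samples$line_id, lines)]
    # silence complement samples of group-specific genes
    grp_dim <- c(D = "tolerance", S = "tolerance", WW = "condition",
                 WS = "condition", P = "generation", RIL = "generation")
    for (g in names(grp_dim)) {
      gi <- which(spec_group == g)
      if (!length(gi)) next
      out_samp <- samples[[grp_dim[[g]]]] != g
      mu_fpkm[gi, out_samp] <- 0
    }
    mu_counts <- sweep(mu_fpkm * cfg$depth_per_fpkm, 2, sf, `*`)
    counts <- matrix(rnbinom(n * ns, mu = as.vector(mu_counts),
                             size = rep(1 / disp, ns)), nrow = n)
    counts[mu_counts == 0] <- 0L
    fpkm <- sweep(counts / cfg$depth_per_fpkm, 2, sf, `/`)
    dimnames(counts) <- dimnames(fpkm) <- list(ids, samples$sample_id)
    truth <- data.frame(gene_id = ids,
                        biotype = ann$genes$biotype,
                        de_label = label, lfc = lfc,
                        specific_group = spec_group,
                        housekeeping = hk,
                        base_fpkm = base,
                        stringsAsFactors = FALSE)
    list(counts = counts, fpkm = fpkm, size_factors = setNames(sf, samples$sample_id),
         truth = truth)
  })
}

## ---- cascade features ------------------------------------------------------

#' Generate per-transcript cascade evidence with planted decoys
#'
#' Transcripts of planted lncRNA genes satisfy every cascade predicate;
#' coding transcripts fail the coding-potential consensus; each decoy
#' violates exactly one named stage so per-stage elimination counts are
#' known in advance.
#'
#' @param cfg A [sim_config()].
#' @param ann A [gene_annotation].
#' @param include_coding Include coding transcripts (eliminated at the
#'   consensus stage) in the feature table.
#' @return list with `features` (data.frame of transcript evidence) and
#'   `truth` (planted stage_of_elimination per transcript).
#' @export
generate_cascade_features <- function(cfg, ann, include_coding = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "gene_annotation"))
  with_seed(derive_seed(cfg$seed, "cascade"), {
    txlen <- transcript_lengths(ann)
    tx <- ann$transcripts
    bt <- setNames(ann$genes$biotype, ann$genes$gene_id)[tx$gene_id]
    keep <- if (include_coding) rep(TRUE, nrow(tx)) else bt != "coding"
    tx <- tx[keep, , drop = FALSE]; bt <- bt[keep]
    n <- nrow(tx)
    is_lnc <- bt != "coding"
    weak_hit <- is_lnc & runif(n) < 0.3
    feats <- data.frame(
      transcript_id = tx$transcript_id,
      gene_id = tx$gene_id,
      length_nt = as.integer(txlen[tx$transcript_id]),
      noncoding_call_a = is_lnc,
      noncoding_call_b = is_lnc,
      hit_identity = ifelse(weak_hit, runif(n, 20, 60), NA_real_),
      hit_aa = ifelse(weak_hit, round(runif(n, 10, 60)), NA_real_),
      hit_evalue = ifelse(weak_hit, 10^runif(n, -6, -1), NA_real_),
      rnc_abundance = ifelse(is_lnc, runif(n, 0, 0.08), runif(n, 1, 20)),
      rna_abundance = ifelse(is_lnc, runif(n, 0.2, 5), runif(n, 1, 50)),
      stringsAsFactors = FALSE)
    # coding transcripts carry strong protein evidence too
    feats$hit_identity[!is_lnc] <- runif(sum(!is_lnc), 70, 100)
    feats$hit_aa[!is_lnc] <- round(runif(sum(!is_lnc), 50, 400))
    feats$hit_evalue[!is_lnc] <- 10^runif(sum(!is_lnc), -60, -20)
    truth <- data.frame(transcript_id = feats$transcript_id,
                        planted_stage = ifelse(is_lnc, "retained", "noncoding_consensus"),
                        stringsAsFactors = FALSE)
    stages <- c("noncoding_consensus", "no_protein_hit", "not_translated",
                "length_and_abundance")
    k <- cfg$n_decoys_per_stage
    if (k > 0) {
      mk_decoy <- function(stage, i) {
        d <- data.frame(transcript_id = sprintf("DECOY_%s_%02d", stage, i),
                        gene_id = sprintf("DECOYG_%s_%02d", stage, i),
                        length_nt = as.integer(round(runif(1, 400, 2000))),
                        noncoding_call_a = TRUE, noncoding_call_b = TRUE,
                        hit_identity = NA_real_, hit_aa = NA_real_,
                        hit_evalue = NA_real_,
                        rnc_abundance = runif(1, 0, 0.08),
                        rna_abundance = runif(1, 0.5, 5),
                        stringsAsFactors = FALSE)
        switch(stage,
          noncoding_consensus = { d$noncoding_call_a <- FALSE },
          no_protein_hit = {
            d$hit_identity <- runif(1, 65, 95)
            d$hit_aa <- round(runif(1, 31, 200))
            d$hit_evalue <- 10^runif(1, -30, -9.5)
          },
          not_translated = { d$rnc_abundance <- runif(1, 0.2, 2) },
          length_and_abundance = {
            if (i %% 2 == 0) d$length_nt <- as.integer(round(runif(1, 50, 200)))
            else d$rna_abundance <- runif(1, 0, 0.1)
          })
        d
      }
      for (stage in stages) for (i in seq_len(k)) {
        feats <- rbind(feats, mk_decoy(stage, i))
        truth <- rbind(truth, data.frame(
          transcript_id = sprintf("DECOY_%s_%02d", stage, i),
          planted_stage = stage, stringsAsFactors = FALSE))
      }
    }
    rownames(feats) <- rownames(truth) <- NULL
    list(features = feats, truth = truth)
  })
}

## ---- coverage tracks -------------------------------------------------------

#' Generate per-mark, per-condition coverage tracks
#'
#' Per-mark signal = body level + strand-aware Gaussian TSS peak (+ 3' peak
#' for m6A on mRNA, restricted to exons) + water-stress shift + small
#' Gaussian bin noise.
#'
#' @param cfg A [sim_config()].
#' @param ann A [gene_annotation].
#' @return list with `tracks` (`tracks[[mark]][[condition]]`, each a
#'   [coverage_track]) and `truth` (the mark parameter table).
#' @export
generate_tracks <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "gene_annotation"))
  with_seed(derive_seed(cfg$seed, "tracks"), {
    sl <- GenomeInfoDb::seqlengths(ann$genes)
    if (anyNA(sl)) sl <- tapply(end(ann$genes), as.character(seqnames(ann$genes)), max) + 5000
    bin <- cfg$track_bin
    genes <- ann$genes
    is_lnc <- genes$biotype != "coding"
    mp <- cfg$mark_profiles
    gauss_add <- function(v, center, height, sd_bp) {
      if (height <= 0) return(v)
      lo <- max(1L, as.integer(floor((center - 4 * sd_bp) / bin)) + 1L)
      hi <- min(length(v), as.integer(ceiling((center + 4 * sd_bp) / bin)))
      if (lo > hi) return(v)
      mid <- (seq(lo, hi) - 0.5) * bin
      v[lo:hi] <- v[lo:hi] + height * exp(-((mid - center)^2) / (2 * sd_bp^2))
      v
    }
    tx_of_gene <- setNames(ann$transcripts$transcript_id, ann$transcripts$gene_id)
    tracks <- list()
    for (mi in seq_len(nrow(mp))) {
      m <- mp[mi, ]
      for (cond in c("WW", "WS")) {
        shift <- if (cond == "WS") m$ws_shift else 0
        vlist <- lapply(sl, function(L) numeric(ceiling(L / bin)))
        names(vlist) <- names(sl)
        for (gi in seq_along(genes)) {
          chrom <- as.character(seqnames(genes)[gi])
          v <- vlist[[chrom]]
          body <- max(0, (if (is_lnc[gi]) m$body_lnc else m$body_coding) + shift)
          minus <- as.character(strand(genes)[gi]) == "-"
          tss <- if (minus) end(genes)[gi] else start(genes)[gi]
          end3 <- if (minus) start(genes)[gi] else end(genes)[gi]
          if (m$mark == "m6A") {
            # RNA-level signal: body over exons only, 3' peak at transcript end
            ex <- ann$exons[[tx_of_gene[[genes$gene_id[gi]]]]]
            for (e in seq_along(ex)) {
              lo <- (start(ex)[e] - 1L) %/% bin + 1L
              hi <- min(length(v), (end(ex)[e] - 1L) %/% bin + 1L)
              v[lo:hi] <- v[lo:hi] + body
            }
            h3 <- (if (is_lnc[gi]) m$end3_height_lnc else m$end3_height_coding)
            if (h3 > 0) v <- gauss_add(v, end3, max(0, h3 + shift), m$tss_sd)
          } else {
            lo <- (start(genes)[gi] - 1L) %/% bin + 1L
            hi <- min(length(v), (end(genes)[gi] - 1L) %/% bin + 1L)
            v[lo:hi] <- v[lo:hi] + body
            h <- (if (is_lnc[gi]) m$tss_height_lnc else m$tss_height_coding)
            if (h > 0) v <- gauss_add(v, tss, max(0, h + shift), m$tss_sd)
          }
          vlist[[chrom]] <- v
        }
        grl <- lapply(names(vlist), function(chrom) {
          v <- vlist[[chrom]]
          if (cfg$track_noise_sd > 0)
            v <- pmax(0, v + rnorm(length(v), 0, cfg$track_noise_sd))
          nb <- length(v)
          GRanges(chrom,
                  IRanges(start = (seq_len(nb) - 1L) * bin + 1L,
                          end = pmin(seq_len(nb) * bin, sl[[chrom]])),
                  score = v, seqlengths = sl)
        })
        gr <- do.call(c, grl)
        gr <- gr[gr$score != 0]
        tracks[[m$mark]][[cond]] <- coverage_track(gr, seqlengths = sl)
      }
    }
    list(tracks = tracks, truth = mp)
  })
}

## ---- population data -------------------------------------------------------

#' Generate recombination fragments, SNP tables and trait tables
#'
#' Fragments are assigned to RIL lines; significant trait-associated SNPs
#' are planted inside lncRNA loci at `sig_snp_rate_lnc` per kb and inside
#' coding loci at `sig_snp_rate_lnc / snp_enrichment` per kb with
#' genotype-dependent trait means in the natural panel; all other SNPs are
#' null (association p uniform, no trait effect).
#'
#' @param cfg A [sim_config()].
#' @param ann A [gene_annotation].
#' @param samples A sample sheet (for the per-sample trait table).
#' @return list with `fragments` (GRanges + line_id), `snps` (data.frame with
#'   per-line genotypes and per-trait association p), `genotypes` (SNP x
#'   panel-line matrix of allele counts), `panel_traits`, `sample_traits`
#'   and `truth` (planted significant SNP ids).
#' @export
generate_population_data <- function(cfg, ann, samples = generate_samples(cfg)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "gene_annotation"))
  with_seed(derive_seed(cfg$seed, "population"), {
    sl <- GenomeInfoDb::seqlengths(ann$genes)
    if (anyNA(sl)) sl <- tapply(end(ann$genes), as.character(seqnames(ann$genes)), max)
    rils <- unique(samples$line_id[samples$generation == "RIL"])
    # recombination fragments
    chrom <- sample(names(sl), cfg$n_fragments, replace = TRUE,
                    prob = as.numeric(sl) / sum(as.numeric(sl)))
    flen <- as.integer(round(runif(cfg$n_fragments, 500, 2000)))
    fst <- as.integer(floor(runif(cfg$n_fragments) * (sl[chrom] - flen))) + 1L
    fragments <- GRanges(chrom, IRanges(fst, fst + flen - 1L))
    fragments$line_id <- sample(rils, cfg$n_fragments, replace = TRUE)

    genes <- ann$genes
    is_lnc <- genes$biotype != "coding"
    place_in <- function(gr, n) {
      if (n == 0L || length(gr) == 0L) return(NULL)
      w <- width(gr)
      gi <- sample(seq_along(gr), n, replace = TRUE, prob = w / sum(w))
      pos <- start(gr)[gi] + as.integer(floor(runif(n) * w[gi]))
      data.frame(chrom = as.character(seqnames(gr))[gi], pos = pos,
                 gene_id = gr$gene_id[gi], stringsAsFactors = FALSE)
    }
    kb_lnc <- sum(width(genes[is_lnc])) / 1000
    kb_cod <- sum(width(genes[!is_lnc])) / 1000
    n_sig_lnc <- as.integer(round(cfg$sig_snp_rate_lnc * kb_lnc))
    n_sig_cod <- as.integer(round(cfg$sig_snp_rate_lnc / cfg$snp_enrichment * kb_cod))
    sig_l <- place_in(genes[is_lnc], n_sig_lnc)
    sig_c <- place_in(genes[!is_lnc], n_sig_cod)
    n_null <- cfg$n_snps
    null_chrom <- sample(names(sl), n_null, replace = TRUE,
                         prob = as.numeric(sl) / sum(as.numeric(sl)))
    null_pos <- as.integer(floor(runif(n_null) * sl[null_chrom])) + 1L
    snps <- rbind(
      if (!is.null(sig_l)) data.frame(sig_l[, c("chrom", "pos")], planted = "lnc") else NULL,
      if (!is.null(sig_c)) data.frame(sig_c[, c("chrom", "pos")], planted = "coding") else NULL,
      data.frame(chrom = null_chrom, pos = null_pos, planted = "null"))
    n_snp <- nrow(snps)
    snps$snp_id <- sprintf("SNP%06d", seq_len(n_snp))
    sig <- snps$planted != "null"
    snps$assoc_p_survival <- ifelse(sig, 10^runif(n_snp, -12, -6), runif(n_snp))
    snps$assoc_p_oil <- runif(n_snp)
    snps$alleles <- "A/G"
    # natural-panel genotypes (allele counts 0/1/2, HWE at random MAF)
    panel <- sprintf("NP%03d", seq_len(cfg$n_panel))
    maf <- runif(n_snp, 0.1, 0.5)
    geno <- matrix(rbinom(n_snp * cfg$n_panel, 2,
                          rep(maf, cfg$n_panel)), nrow = n_snp)
    dimnames(geno) <- list(snps$snp_id, panel)
    survival <- rnorm(cfg$n_panel, 50, cfg$trait_noise_sd)
    # a small causal subset (planted lncRNA SNPs first) actually drives the
    # trait; the remaining planted SNPs keep their significant association p
    # as consumed input
    causal <- head(which(snps$planted == "lnc"), 10L)
    if (!length(causal)) causal <- head(which(sig), 10L)
    for (i in causal)
      survival <- survival + cfg$assoc_beta * (geno[i, ] - 2 * maf[i])
    oil <- rnorm(cfg$n_panel, 4, 0.5)
    panel_traits <- data.frame(line_id = panel, survival = survival, oil = oil,
                               stringsAsFactors = FALSE)
    # per-RNA-sample traits: tolerance class and stress shift the means
    st_mean <- 70 - 25 * (samples$tolerance == "S") - 10 * (samples$condition == "WS")
    sample_traits <- data.frame(
      sample_id = samples$sample_id,
      survival = rnorm(nrow(samples), st_mean, 8),
      root_dw = rnorm(nrow(samples), 5 - 1.5 * (samples$condition == "WS"), 1),
      plant_height = rnorm(nrow(samples), 60 - 8 * (samples$condition == "WS"), 6),
      stringsAsFactors = FALSE)
    truth <- data.frame(snp_id = snps$snp_id, planted = snps$planted,
                        causal = seq_len(n_snp) %in% causal,
                        stringsAsFactors = FALSE)
    snps <- snps[, c("snp_id", "chrom", "pos", "alleles",
                     "assoc_p_survival", "assoc_p_oil")]
    list(fragments = fragments, snps = snps, genotypes = geno,
         panel_traits = panel_traits, sample_traits = sample_traits,
         truth = truth)
  })
}

## ---- miRNA target tables ---------------------------------------------------

#' Generate miRNA-target tables with planted ceRNA bridges
#'
#' Each planted bridge is an (ncRNA, miRNA, mRNA) triple whose two edges are
#' guaranteed present; distractor rows use miRNA namespaces that never cross
#' RNA classes, so they can never form a bridge.
#'
#' @param cfg A [sim_config()].
#' @return list with `lnc_mir`, `circ_mir`, `mrna_mir` tables and `truth`
#'   (planted bridge triples).
#' @export
generate_mirna_targets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "mirna"), {
    itypes <- c("cleavage", "translation_inhibition", "mimic")
    nb <- cfg$n_bridges
    empty <- function() data.frame(rna_id = character(0), rna_type = character(0),
                                   mirna_id = character(0), interaction = character(0),
                                   stringsAsFactors = FALSE)
    lnc_mir <- circ_mir <- mrna_mir <- empty()
    truth <- data.frame(ncrna_id = character(0), ncrna_type = character(0),
                        mirna_id = character(0), mrna_id = character(0),
                        stringsAsFactors = FALSE)
    if (nb > 0) {
      for (b in seq_len(nb)) {
        nct <- if (b %% 3 == 0) "circRNA" else "lncRNA"
        ncid <- if (nct == "circRNA") sprintf("circRNA-2_%07d", b) else sprintf("XLOC_B%05d", b)
        mir <- sprintf("zma-miR%03d-5p", b)
        mrna <- sprintf("Zm00001d%06d", b)
        edge1 <- data.frame(rna_id = ncid, rna_type = nct, mirna_id = mir,
                            interaction = sample(itypes, 1), stringsAsFactors = FALSE)
        if (nct == "circRNA") circ_mir <- rbind(circ_mir, edge1)
        else lnc_mir <- rbind(lnc_mir, edge1)
        mrna_mir <- rbind(mrna_mir, data.frame(
          rna_id = mrna, rna_type = "mRNA", mirna_id = mir,
          interaction = sample(itypes, 1), stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(ncrna_id = ncid, ncrna_type = nct,
                                         mirna_id = mir, mrna_id = mrna,
                                         stringsAsFactors = FALSE))
      }
    }
    nd <- cfg$n_distractors
    if (nd > 0) {
      mk <- function(prefix, type, mirns) data.frame(
        rna_id = sprintf("%s%05d", prefix, seq_len(nd)),
        rna_type = type,
        mirna_id = sprintf("zma-miR%s%04d", mirns, sample(seq_len(nd * 2), nd)),
        interaction = sample(itypes, nd, replace = TRUE),
        stringsAsFactors = FALSE)
      lnc_mir <- rbind(lnc_mir, mk("XLOC_D", "lncRNA", "L"))
      circ_mir <- rbind(circ_mir, mk("circRNA-D", "circRNA", "C"))
      mrna_mir <- rbind(mrna_mir, mk("Zm_D", "mRNA", "M"))
    }
    list(lnc_mir = lnc_mir, circ_mir = circ_mir, mrna_mir = mrna_mir,
         truth = truth)
  })
}
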