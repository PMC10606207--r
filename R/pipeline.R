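# End-to-end orchestration: simulate inputs, run every analysis stage in
# dependency order, aggregate a machine-readable summary. A single master
# seed determines everything; each stage derives its own sub-seed, so
# toggling one stage never perturbs another stage's randomness.

#' Pipeline configuration
#'
#' @param seed Master seed (drives the simulation and all stages).
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param out_dir Optional output directory; when given, stage artifacts
#'   (GTF, TSVs, BED, summary JSON and the serialized config) are written.
#' @param stages Named logical vector toggling analysis stages.
#' @param expr_threshold Expression threshold (FPKM) for expressed /
#'   specific calls.
#' @param de_alpha Adjusted-p cutoff for DE status.
#' @param snp_alpha Association-p cutoff for significant SNPs.
#' @param profile_marks Marks profiled in the epigenome stage.
#' @param min_module_size,beta,cut_height Module-detection parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            out_dir = NULL,
                            stages = c(identify = TRUE, expression = TRUE,
                                       recombination = TRUE, profiles = TRUE,
                                       association = TRUE, networks = TRUE),
                            expr_threshold = 0.1,
                            de_alpha = 0.05,
                            snp_alpha = 1e-5,
                            profile_marks = c("H3K4me3", "H3K9ac", "m6A"),
                            min_module_size = 30L, beta = 6, cut_height = 0.6) {
  def <- c(identify = TRUE, expression = TRUE, recombination = TRUE,
           profiles = TRUE, association = TRUE, networks = TRUE)
  def[names(stages)] <- stages
  cfg <- list(seed = as.integer(seed), sim = sim, out_dir = out_dir,
              stages = def, expr_threshold = expr_threshold,
              de_alpha = de_alpha, snp_alpha = snp_alpha,
              profile_marks = profile_marks,
              min_module_size = min_module_size, beta = beta,
              cut_height = cut_height)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates inputs under the configured seed, then runs identification,
#' expression statistics, recombination overlap, epigenome profiling,
#' association and network stages (each toggleable). Rerunning with the
#' same config reproduces the summary exactly.
#'
#' @param config A [pipeline_config()].
#' @return list of class `pipeline_result` with `summary` (aggregated
#'   statistics), `data` (the simulated inputs and truth sidecars) and
#'   per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  res <- list()
  summary <- list(seed = config$seed)

  samples <- generate_samples(cfg)
  ann_gen <- generate_annotation(cfg)
  ann <- ann_gen$annotation
  expr <- generate_expression(cfg, ann, samples)
  res$data <- list(samples = samples, annotation = ann,
                   annotation_truth = ann_gen$truth, expression = expr)
  genes <- ann$genes
  is_lnc <- genes$biotype != "coding"
  lnc_ids <- genes$gene_id[is_lnc]
  summary$n_genes <- length(genes)
  summary$n_lnc_genes <- sum(is_lnc)
  summary$n_coding_genes <- sum(!is_lnc)

  if (config$stages[["identify"]]) {
    feats <- generate_cascade_features(cfg, ann)
    casc <- run_cascade(feats$features)
    cls <- classify_position(genes[is_lnc], ann)
    ctab <- table(factor(cls$class, c("intergenic", "antisense", "divergent",
                                      "intronic", "sense_overlapping")))
    cnt <- count_expressed(expr$fpkm, samples, threshold = config$expr_threshold)
    res$identify <- list(features = feats, cascade = casc, classes = cls,
                         expressed = cnt)
    summary$cascade_counts <- setNames(as.list(casc$per_stage_counts$surviving),
                                       casc$per_stage_counts$stage)
    summary$n_retained <- length(casc$retained)
    summary$class_pct <- as.list(setNames(
      vapply(as.integer(ctab), proportion, numeric(1),
             denominator = sum(ctab)), names(ctab)))
    summary$pct_single_exon_lnc <- proportion(
      sum(exon_counts(ann)[paste0(lnc_ids, "_T1")] == 1), length(lnc_ids))
    summary$mean_expressed_per_sample <- mean(cnt$per_sample)
  }

  if (config$stages[["expression"]]) {
    de <- run_de(expr$counts, samples)
    de$biotype <- ifelse(de$gene_id %in% lnc_ids, "lncRNA", "coding")
    # Table-1-style gene x line status counts per biotype
    tab <- matrix(0, 2, 3, dimnames = list(c("lncRNA", "coding"),
                                           c("up", "down", "equal")))
    tt <- table(de$biotype, de$status)
    tab[rownames(tt), colnames(tt)] <- tt
    de_tab <- contingency(tab[c("lncRNA", "coding"), c("up", "down")])
    # DE in at least one line
    de_any <- tapply(de$status != "equal", de$gene_id, any)
    # entropy over per-line mean expression (N = number of lines), the
    # scale on which housekeeping genes concentrate at log2(N)
    lines <- unique(samples$line_id)
    line_fpkm <- vapply(lines, function(L)
      rowMeans(expr$fpkm[, samples$sample_id[samples$line_id == L],
                         drop = FALSE]), numeric(nrow(expr$fpkm)))
    ent <- shannon_entropy(line_fpkm)
    hk <- select_housekeeping(expr$fpkm)
    spec <- list(tolerance = call_specific(expr$fpkm, samples, "tolerance",
                                           config$expr_threshold),
                 condition = call_specific(expr$fpkm, samples, "condition",
                                          config$expr_threshold),
                 generation = call_specific(expr$fpkm, samples, "generation",
                                           config$expr_threshold))
    res$expression <- list(de = de, table = tab, up_down_test = de_tab,
                           entropy = ent, housekeeping = hk, specific = spec)
    H <- setNames(ent$H, ent$gene_id)
    summary$de <- list(
      status_counts = apply(tab, 1, as.list),
      pct_up_lnc = proportion(tab["lncRNA", "up"], sum(tab["lncRNA", ])),
      pct_down_lnc = proportion(tab["lncRNA", "down"], sum(tab["lncRNA", ])),
      pct_up_coding = proportion(tab["coding", "up"], sum(tab["coding", ])),
      pct_down_coding = proportion(tab["coding", "down"], sum(tab["coding", ])),
      up_down_chi2_p = de_tab$p,
      pct_de_lnc = proportion(sum(de_any[lnc_ids]), length(lnc_ids)),
      pct_de_coding = proportion(sum(de_any[setdiff(names(de_any), lnc_ids)]),
                                 length(setdiff(names(de_any), lnc_ids))))
    summary$entropy <- list(
      median_H_lnc = median(H[intersect(lnc_ids, names(H))]),
      median_H_coding = median(H[setdiff(names(H), lnc_ids)]),
      median_H_housekeeping = if (length(hk)) median(H[intersect(hk, names(H))]) else NA,
      max_H = log2(length(lines)))
    summary$specific <- list(
      pct_lnc_tolerance_specific = proportion(
        sum(c(spec$tolerance$D, spec$tolerance$S) %in% lnc_ids), length(lnc_ids)),
      pct_coding_tolerance_specific = proportion(
        sum(!(c(spec$tolerance$D, spec$tolerance$S) %in% lnc_ids)),
        summary$n_coding_genes),
      n_ws_specific_lnc = sum(spec$condition$WS %in% lnc_ids),
      n_ww_specific_lnc = sum(spec$condition$WW %in% lnc_ids),
      pct_lnc_ril_specific = proportion(sum(spec$generation$RIL %in% lnc_ids),
                                        length(lnc_ids)))
  }

  if (config$stages[["recombination"]]) {
    if (!config$stages[["expression"]])
      stopf("recombination stage requires the expression stage")
    pop <- generate_population_data(cfg, ann, samples)
    res$population <- pop
    ov <- overlap_fragments(ann, pop$fragments)
    enr <- recomb_enrichment(ov, res$expression$specific$generation,
                             all_genes = data.frame(gene_id = genes$gene_id,
                                                    biotype = genes$biotype,
                                                    stringsAsFactors = FALSE))
    res$recombination <- list(overlaps = ov, enrichment = enr)
    summary$recombination <- list(
      n_overlapping_lnc = sum(ov$biotype != "coding"),
      n_overlapping_coding = sum(ov$biotype == "coding"),
      pct_multiple_lnc = if (any(ov$biotype != "coding"))
        proportion(sum(ov$multiplicity == "multiple" & ov$biotype != "coding"),
                   sum(ov$biotype != "coding")) else NA,
      ril_specific_pct_lnc = enr$proportions[["lncRNA"]],
      ril_specific_pct_coding = enr$proportions[["coding"]],
      enrichment_p = if (!is.null(enr$report)) enr$report$p else NA)
  }

  if (config$stages[["profiles"]]) {
    trk <- generate_tracks(cfg, ann)
    res$tracks <- trk
    lay <- metagene_layout()
    profs <- list()
    for (mark in intersect(config$profile_marks, names(trk$tracks))) {
      for (cond in c("WW", "WS")) {
        t1 <- trk$tracks[[mark]][[cond]]
        if (mark == "m6A") {
          profs[[mark]][[cond]] <- list(
            coding = transcript_profile_m6a(
              t1, ann, paste0(genes$gene_id[!is_lnc], "_T1"),
              gene_class = "coding", condition = cond),
            lncRNA = transcript_profile_m6a(
              t1, ann, paste0(lnc_ids, "_T1"),
              gene_class = "lncRNA", condition = cond))
        } else {
          profs[[mark]][[cond]] <- list(
            coding = metagene(t1, genes[!is_lnc], lay, mark, "coding", cond),
            lncRNA = metagene(t1, genes[is_lnc], lay, mark, "lncRNA", cond))
        }
      }
    }
    res$profiles <- profs
    peak_bin <- function(p) which.max(p$bins$mean_signal)
    summary$profiles <- lapply(profs, function(bycond) {
      ww <- bycond$WW; ws <- bycond$WS
      list(peak_bin_coding = peak_bin(ww$coding),
           peak_bin_lnc = peak_bin(ww$lncRNA),
           peak_height_coding = max(ww$coding$bins$mean_signal),
           peak_height_lnc = max(ww$lncRNA$bins$mean_signal),
           ws_tss_shift_coding =
             compare_profiles(ww$coding, ws$coding)$tss_mean_diff)
    })
    # H3K9ac at lncRNA TSS: drought-sensitive-specific vs tolerant-specific
    if ("H3K9ac" %in% names(trk$tracks) && config$stages[["expression"]]) {
      spec <- res$expression$specific$tolerance
      dg <- intersect(spec$D, lnc_ids); sg <- intersect(spec$S, lnc_ids)
      if (length(dg) >= 2 && length(sg) >= 2) {
        gset <- genes[match(c(dg, sg), genes$gene_id)]
        grp <- c(rep("D", length(dg)), rep("S", length(sg)))
        gs_test <- lapply(c(WW = "WW", WS = "WS"), function(cond) {
          sig <- region_signal(trk$tracks$H3K9ac[[cond]], gset, "tss")
          group_signal_test(sig$mean_signal, grp)
        })
        res$h3k9ac_group_test <- gs_test
        summary$h3k9ac_S_minus_D <- lapply(gs_test, function(z)
          list(diff = z$diff, p = z$p))
      }
    }
  }

  if (config$stages[["association"]]) {
    if (is.null(res$population))
      res$population <- generate_population_data(cfg, ann, samples)
    pop <- res$population
    mc <- match_controls(lnc_ids, genes$gene_id[!is_lnc], expr$fpkm)
    d_lnc <- snp_density(genes[is_lnc], pop$snps, "survival", config$snp_alpha)
    d_ctl <- snp_density(genes[match(mc$controls, genes$gene_id)], pop$snps,
                         "survival", config$snp_alpha)
    d_lnc_oil <- snp_density(genes[is_lnc], pop$snps, "oil", config$snp_alpha)
    # genotype-trait tests for significant SNPs inside lncRNA genes
    sig <- pop$snps[pop$snps$assoc_p_survival < config$snp_alpha, , drop = FALSE]
    gt <- list()
    if (nrow(sig)) {
      sgr <- GRanges(sig$chrom, IRanges(sig$pos, sig$pos))
      inside <- sig$snp_id[countOverlaps(sgr, genes[is_lnc],
                                         ignore.strand = TRUE) > 0]
      for (sid in head(inside, 5)) {
        tr <- pop$panel_traits$survival[match(colnames(pop$genotypes),
                                              pop$panel_traits$line_id)]
        gt[[sid]] <- genotype_trait_test(pop$genotypes[sid, ], tr)
      }
    }
    res$association <- list(controls = mc, density_lnc = d_lnc,
                            density_controls = d_ctl,
                            density_lnc_oil = d_lnc_oil,
                            genotype_tests = gt)
    summary$association <- list(
      snps_per_kb_lnc = d_lnc$snps_per_kb,
      snps_per_kb_controls = d_ctl$snps_per_kb,
      density_ratio = if (d_ctl$snps_per_kb > 0)
        d_lnc$snps_per_kb / d_ctl$snps_per_kb else NA,
      snps_per_kb_lnc_oil = d_lnc_oil$snps_per_kb,
      control_match_quality = mc$mean_abs_delta,
      n_genotype_tests_significant = sum(vapply(gt, function(z) z$p < 0.05,
                                                logical(1))))
  }

  if (config$stages[["networks"]]) {
    if (!config$stages[["expression"]])
      stopf("networks stage requires the expression stage")
    de <- res$expression$de
    deg <- unique(de$gene_id[de$status != "equal"])
    summary$networks <- list()
    if (length(deg) >= config$min_module_size) {
      em <- log2(expr$fpkm[deg, , drop = FALSE] + 1)
      mods <- detect_modules(em, config$min_module_size, config$beta,
                             config$cut_height)
      st <- res$population$sample_traits %||%
        generate_population_data(cfg, ann, samples)$sample_traits
      mt <- if (!is.null(mods$eigengenes))
        module_trait(mods, st[match(rownames(mods$eigengenes), st$sample_id), ])
      else NULL
      mg <- NULL
      if (!is.null(mt) && nrow(mt$retained)) {
        m1 <- mt$retained$module[which.max(abs(mt$retained$r))]
        tr1 <- mt$retained$trait[which.max(abs(mt$retained$r))]
        mg <- mm_gs(em[mods$modules == m1, , drop = FALSE],
                    st[[tr1]][match(colnames(em), st$sample_id)])
      }
      res$networks <- list(modules = mods, module_trait = mt, mm_gs = mg)
      summary$networks$n_modules <- sum(names(mods$sizes) != "grey")
      summary$networks$n_module_trait_retained <-
        if (!is.null(mt)) nrow(mt$retained) else 0L
      summary$networks$top_module_mm_gs_cor <-
        if (!is.null(mg)) mg$cor_mm_gs else NA
      summary$networks$n_lnc_in_modules <-
        sum(names(mods$modules)[mods$modules != "grey"] %in% lnc_ids)
    }
    mir <- generate_mirna_targets(cfg)
    net <- build_cerna(mir$lnc_mir, mir$circ_mir, mir$mrna_mir)
    res$cerna <- list(inputs = mir, network = net)
    summary$networks$cerna <- c(net$stats[c("n_lncRNA", "n_circRNA", "n_mRNA",
                                            "n_miRNA", "n_edges")],
                                list(n_bridges = nrow(net$bridges)))
  }

  out <- structure(list(summary = summary, config = config, results = res),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  genes: %d coding + %d lncRNA; stages run: %s\n",
              x$summary$n_coding_genes, x$summary$n_lnc_genes,
              paste(names(which(x$config$stages)), collapse = ", ")))
  invisible(x)
}

# Serialize stage artifacts + summary + config for provenance.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- result$results
  write_annotation(res$data$annotation, file.path(out_dir, "annotation.gtf"))
  write_expression(res$data$expression$fpkm, file.path(out_dir, "fpkm.tsv"))
  write_expression(res$data$expression$counts, file.path(out_dir, "counts.tsv"))
  write.table(res$data$samples, file.path(out_dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$population))
    write_intervals(res$population$fragments, file.path(out_dir, "fragments.bed"))
  if (!is.null(res$expression))
    write.table(res$expression$de, file.path(out_dir, "de.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$identify))
    write.table(res$identify$classes, file.path(out_dir, "positional_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(list(summary = result$summary, config = cfg),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(out_dir)
}
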