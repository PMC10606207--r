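make_genes <- function(start, end, strand, chrom = "chr1") {
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  g$gene_id <- sprintf("g%d", seq_along(g))
  g
}

test_that("a flat track yields a constant profile in every bin", {
  trk <- flat_track(2.5, len = 20000)
  g <- make_genes(c(5000, 12000), c(7000, 13500), c("+", "-"))
  p <- metagene(trk, g, metagene_layout())
  expect_true(all(abs(p$bins$mean_signal - 2.5) < 1e-12))
  expect_equal(nrow(p$bins), 20 + 40 + 20)
})

test_that("a planted TSS peak is recovered at the TSS-adjacent bin on both strands", {
  len <- 30000
  v <- numeric(len)
  add_peak <- function(v, center, h = 5, s = 100) {
    i <- pmax(1, center - 400):pmin(len, center + 400)
    v[i] <- v[i] + h * exp(-((i - center)^2) / (2 * s^2))
    v
  }
  gp <- make_genes(5000, 8000, "+")     # TSS at 5000
  gm <- make_genes(20000, 23000, "-")   # TSS at 23000
  v <- add_peak(v, 5000); v <- add_peak(v, 23000)
  trk <- vector_track(v)
  lay <- metagene_layout()
  tss_bins <- c(lay$n_up, lay$n_up + 1L)  # peak centered on the up/body boundary
  for (g in list(gp, gm)) {
    p <- metagene(trk, g, lay)
    expect_true(which.max(p$bins$mean_signal) %in%
                  c(tss_bins[1] - 1L, tss_bins, tss_bins[2] + 1L))
  }
  # minus-strand gene with signal at its genomic end shows it at the 5' side
  pm <- metagene(trk, gm, lay)
  first_half <- sum(pm$bins$mean_signal[1:40])
  second_half <- sum(pm$bins$mean_signal[41:80])
  expect_gt(first_half, second_half)
})

test_that("profiles are linear over disjoint gene-set unions", {
  withr::with_seed(61, {
    v <- pmax(0, rnorm(50000, 1, 0.3))
    trk <- vector_track(v)
    g1 <- make_genes(c(2000, 9000), c(4000, 10500), c("+", "-"))
    g2 <- make_genes(c(20000, 30000, 40000), c(22000, 31000, 43000),
                     c("-", "+", "+"))
    lay <- metagene_layout()
    p1 <- metagene(trk, g1, lay)$bins$mean_signal
    p2 <- metagene(trk, g2, lay)$bins$mean_signal
    pu <- metagene(trk, c(g1, g2), lay)$bins$mean_signal
    expect_equal(pu, (2 * p1 + 3 * p2) / 5, tolerance = 1e-12)
  })
})

test_that("mirroring the genome and flipping strands leaves profiles unchanged", {
  withr::with_seed(62, {
    L <- 40000
    v <- pmax(0, rnorm(L, 1, 0.3) + c(rep(0, 10000), rep(0.5, 5000), rep(0, L - 15000)))
    g <- make_genes(c(8000, 26000), c(12000, 28000), c("+", "-"))
    pf <- metagene(vector_track(v), g, metagene_layout())
    vm <- rev(v)
    gm <- GRanges("chr1", IRanges(L - end(g) + 1L, L - start(g) + 1L),
                  strand = ifelse(as.character(strand(g)) == "+", "-", "+"))
    gm$gene_id <- g$gene_id
    pm <- metagene(vector_track(vm), gm, metagene_layout())
    expect_equal(pf$bins$mean_signal, pm$bins$mean_signal, tolerance = 1e-12)
  })
})

test_that("profile comparison is antisymmetric and recovers planted shifts", {
  g <- make_genes(c(5000, 15000), c(8000, 17000), c("+", "-"))
  a <- metagene(flat_track(1, 30000), g)
  b <- metagene(flat_track(1.5, 30000), g)
  d0 <- compare_profiles(a, a)
  expect_true(all(d0$diff$diff == 0))
  dab <- compare_profiles(a, b)
  dba <- compare_profiles(b, a)
  expect_equal(dab$diff$diff, -dba$diff$diff)
  expect_equal(dab$body_mean_diff, 0.5, tolerance = 1e-12)
  lay2 <- metagene_layout(n_body = 10)
  expect_error(compare_profiles(a, metagene(flat_track(1, 30000), g, lay2)),
               "layout")
})

test_that("group signal tests are symmetric and powered for a 1-SD shift", {
  withr::with_seed(63, {
    x <- rnorm(30, 5); y <- rnorm(30, 5)
    r <- group_signal_test(c(x, y), rep(c("D", "S"), each = 30))
    r_same <- group_signal_test(c(x, x), rep(c("D", "S"), each = 30))
    expect_equal(r_same$diff, 0)
    expect_equal(r_same$p, 1)
    # label swap flips the effect sign, keeps p
    r_sw <- group_signal_test(c(y, x), rep(c("D", "S"), each = 30))
    expect_equal(r_sw$diff, -r$diff)
    expect_equal(r_sw$p, r$p)
    expect_error(group_signal_test(c(1, 2, 3), c("D", "S", "S")), ">= 2")
    # power: planted 1-SD shift at n = 50 per group
    hits <- replicate(60, {
      a <- rnorm(50); b <- rnorm(50, 1)
      group_signal_test(c(a, b), rep(c("D", "S"), each = 50))$p < 0.05
    })
    expect_gte(mean(hits), 0.8)
  })
})

test_that("transcript-space m6A profiles splice out introns and keep 3' peaks", {
  # two-exon transcript: exon1 1001-1500, exon2 2501-3000; 3' peak in exon2
  L <- 4000
  v <- numeric(L)
  v[1001:1500] <- 1
  v[2501:3000] <- 1
  v[2900:3000] <- 5
  v[1501:2500] <- 9   # intron signal must NOT appear in transcript space
  trk <- vector_track(v)
  ann <- make_annotation("chr1", 1001, 3000, "+", "gx", "coding",
                         exon_starts = list(c(1001, 2501)),
                         exon_ends = list(c(1500, 3000)))
  p <- transcript_profile_m6a(trk, ann, "gx_T1", n_bins = 20)
  expect_true(which.max(p$bins$mean_signal) >= 19L)     # 3'-terminal bins
  expect_true(all(p$bins$mean_signal <= 5))             # intron excluded
  expect_true(all(p$bins$mean_signal[1:10] <= 1 + 1e-9))

  # single-exon transcript equals the genomic body profile
  ann1 <- make_annotation("chr1", 1001, 1500, "+", "gy", "lncRNA")
  p1 <- transcript_profile_m6a(trk, ann1, "gy_T1", n_bins = 15)
  lay <- metagene_layout(upstream = 100, n_up = 2, n_body = 15, n_down = 2,
                         downstream = 100)
  mg <- metagene(trk, ann1$genes, lay)
  expect_equal(p1$bins$mean_signal,
               mg$bins$mean_signal[mg$bins$region == "body"], tolerance = 1e-12)

  # flat track -> flat transcript profile
  pf <- transcript_profile_m6a(flat_track(2, L), ann, "gx_T1", n_bins = 12)
  expect_true(all(abs(pf$bins$mean_signal - 2) < 1e-12))
})

test_that("generator tracks place recoverable TSS peaks and WS shifts", {
  cfg <- sim_config(seed = 64, n_coding = 40, n_lnc = 15, track_noise_sd = 0.01)
  ann <- generate_annotation(cfg)$annotation
  tr <- generate_tracks(cfg, ann)
  g <- ann$genes
  lay <- metagene_layout()
  for (str in c("+", "-")) {
    sub <- g[g$biotype == "coding" & as.character(strand(g)) == str]
    p <- metagene(tr$tracks$H3K4me3$WW, sub, lay)
    expect_true(abs(which.max(p$bins$mean_signal) - 20.5) <= 1.5)  # within 1 bin of TSS
  }
  # activating mark shifts down under WS; H3K9me3 shifts up
  pc_ww <- metagene(tr$tracks$H3K4me3$WW, g[g$biotype == "coding"], lay)
  pc_ws <- metagene(tr$tracks$H3K4me3$WS, g[g$biotype == "coding"], lay)
  expect_lt(compare_profiles(pc_ww, pc_ws)$tss_mean_diff, 0)
  k9_ww <- metagene(tr$tracks$H3K9me3$WW, g[g$biotype == "coding"], lay)
  k9_ws <- metagene(tr$tracks$H3K9me3$WS, g[g$biotype == "coding"], lay)
  expect_gt(compare_profiles(k9_ww, k9_ws)$body_mean_diff, 0)
  # coding TSS peaks exceed lncRNA TSS peaks
  pl <- metagene(tr$tracks$H3K4me3$WW, g[g$biotype != "coding"], lay)
  expect_gt(max(pc_ww$bins$mean_signal), max(pl$bins$mean_signal))
})
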