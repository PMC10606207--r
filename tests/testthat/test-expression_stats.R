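test_that("the exact NB test is symmetric and handles degenerate genes", {
  r <- test_de(c(100, 100), c(100, 100))
  expect_equal(r$log2fc, 0)
  expect_gt(r$p, 0.9)
  z <- test_de(c(0, 0), c(0, 0))
  expect_equal(z$log2fc, 0)
  expect_equal(z$p, 1)
  expect_error(test_de(c(10), c(10, 10)), "replicates")
  expect_error(test_de(c(-1, 2), c(1, 1)), "nonnegative")
  # swapping conditions mirrors the fold change and keeps the p-value
  a <- test_de(c(50, 60), c(200, 220))
  b <- test_de(c(200, 220), c(50, 60))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_lt(abs(a$log2fc + b$log2fc), 0.02)  # pseudo-count asymmetry only
})

test_that("DE status classification applies both the p and fold-change gates", {
  expect_equal(classify_status(1.2, 0.01), "up")
  expect_equal(classify_status(-0.8, 0.001), "equal")  # fold-change gate
  expect_equal(classify_status(-3, 0.049), "down")
  expect_equal(classify_status(2.5, 0.06), "equal")    # significance gate
  # mirror property
  x <- seq(-3, 3, by = 0.25)
  p <- rep(0.01, length(x))
  flip <- c(up = "down", down = "up", equal = "equal")
  expect_identical(unname(flip[classify_status(x, p)]), classify_status(-x, p))
})

test_that("BH adjustment preserves the p-value ranking", {
  withr::with_seed(42, {
    p <- runif(200)^2
    padj <- p.adjust(p, "BH")
    expect_identical(order(p), order(padj, p))
    expect_true(all(padj >= p))
  })
})

test_that("exact NB p-values track edgeR's exact test on overdispersed counts", {
  withr::with_seed(99, {
    n <- 300
    mu <- rlnorm(n, log(150), 0.7)
    fc <- c(rep(1, 200), rep(4, 50), rep(0.25, 50))
    cnt <- cbind(matrix(rnbinom(2 * n, mu = mu, size = 10), n),
                 matrix(rnbinom(2 * n, mu = mu * fc, size = 10), n))
    dimnames(cnt) <- list(paste0("g", 1:n),
                          c("ww1", "ww2", "ws1", "ws2"))
    phi <- 0.1
    nf <- colSums(cnt) / mean(colSums(cnt))
    mine <- vapply(1:n, function(i)
      test_de(cnt[i, 1:2], cnt[i, 3:4], norm_factors = nf, dispersion = phi)$p,
      numeric(1))
    suppressMessages({
      dge <- edgeR::DGEList(counts = cnt, group = c(1, 1, 2, 2))
      et <- edgeR::exactTest(dge, dispersion = phi)
    })
    expect_gt(cor(rank(mine), rank(et$table$PValue)), 0.95)
    # the two tests call significance concordantly at the 0.05 level
    expect_gt(mean((mine < 0.05) == (et$table$PValue < 0.05)), 0.9)
  })
})

test_that("Shannon entropy matches its closed forms and bounds", {
  expect_equal(shannon_entropy(rep(3.7, 16))$H, 4)      # uniform over 16
  expect_equal(shannon_entropy(c(5, rep(0, 9)))$H, 0)   # single-sample gene
  expect_equal(shannon_entropy(c(0.5, 0.5))$H, 1)
  # all-zero genes excluded with a reason, not assigned H = 0
  m <- rbind(a = c(1, 1), b = c(0, 0))
  r <- shannon_entropy(m)
  expect_equal(r$gene_id, "a")
  expect_equal(attr(r, "excluded"), "b")
  # bounds over random nonnegative matrices
  withr::with_seed(7, {
    X <- matrix(rexp(50 * 12), 50)
    rownames(X) <- paste0("g", 1:50)
    H <- shannon_entropy(X)$H
    expect_true(all(H >= 0 & H <= log2(12) + 1e-12))
  })
})

test_that("specific expression uses >= 1 sample vs zero-complement semantics", {
  md <- two_line_metadata()   # RIL1 = D, RIL2 = S
  f <- matrix(0, 3, 8, dimnames = list(c("gWS", "gLow", "gAll"), md$sample_id))
  f["gWS", md$sample_id[md$condition == "WS"]] <- 5
  f["gLow", ] <- 0.05
  f["gAll", ] <- 2
  sp <- call_specific(f, md, "condition")
  expect_equal(sp$WS, "gWS")
  expect_equal(sp$WW, character(0))
  sp2 <- call_specific(f, md, "tolerance")
  expect_true(!"gLow" %in% unlist(sp2))   # sub-threshold everywhere
  expect_error(call_specific(f, md, "tolerance", genes = "nope"), "absent")
})

test_that("planted group-specific fractions are recovered within binomial error", {
  cfg <- sim_config(seed = 31, n_coding = 100, n_lnc = 300,
                    specific_config = list(
                      lnc = c(D = 0.10, S = 0, WW = 0, WS = 0, P = 0, RIL = 0),
                      coding = c(D = 0, S = 0, WW = 0, WS = 0, P = 0, RIL = 0)))
  ann <- generate_annotation(cfg)$annotation
  s <- generate_samples(cfg)
  ex <- generate_expression(cfg, ann, s)
  sp <- call_specific(ex$fpkm, s, "tolerance")
  lnc_ids <- ann$genes$gene_id[ann$genes$biotype != "coding"]
  frac <- sum(sp$D %in% lnc_ids) / length(lnc_ids)
  # planted 10% at n = 300: keep within 3 binomial SDs (~5 points)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 300))
  truthD <- ex$truth$gene_id[ex$truth$specific_group == "D"]
  expect_true(all(truthD %in% sp$D))
})

test_that("contingency reports match closed-form and flag sparse tables", {
  r0 <- contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_true(all(abs(rowSums(r0$proportions) - 100) < 0.2))
  expect_error(contingency(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  sparse <- contingency(matrix(c(1, 0, 1, 200), 2))
  expect_false(is.null(sparse$warning))
  expect_true(is.finite(sparse$p))
})

test_that("chi-square p agrees with a permutation oracle on small tables", {
  perm_p <- function(tab, n_draws = 1e5) {
    obs <- contingency(tab)
    draws <- r2dtable(n_draws, rowSums(tab), colSums(tab))
    chi <- vapply(draws, function(d)
      suppressWarnings(chisq.test(d, correct = FALSE)$statistic), numeric(1))
    c(asym = obs$p, perm = mean(chi >= obs$chi2 - 1e-9))
  }
  withr::with_seed(123, {
    # n = 40 with the observed configuration in the tail, where the
    # asymptotic approximation is used for inference
    v40 <- perm_p(matrix(c(16, 4, 8, 12), 2, byrow = TRUE))
    expect_lt(abs(v40["asym"] - v40["perm"]), 0.02)
    # at a few hundred observations the agreement holds across the range
    v400 <- perm_p(matrix(c(120, 80, 95, 105), 2, byrow = TRUE))
    expect_lt(abs(v400["asym"] - v400["perm"]), 0.02)
    v400b <- perm_p(matrix(c(115, 85, 90, 110), 2, byrow = TRUE))
    expect_lt(abs(v400b["asym"] - v400b["perm"]), 0.02)
  })
})

test_that("proportions reproduce the published reporting precision", {
  expect_equal(proportion(2809, 7220), 38.9)
  expect_equal(proportion(0, 7220), 0)
  expect_equal(proportion(179, 1923), 9.31)
  expect_error(proportion(5, 0), "denominator")
  expect_error(proportion(8, 5), "numerator")
})

test_that("fold-change distributions expose spread differences between classes", {
  withr::with_seed(55, {
    lfc <- c(rnorm(300, 0, 2), rnorm(300, 0, 1), rep(0, 50))
    cls <- c(rep("lncRNA", 300), rep("coding", 300), rep("housekeeping", 50))
    d <- fc_distribution(lfc, cls)
    expect_gt(d$lncRNA$iqr, d$coding$iqr)
    expect_equal(d$housekeeping$iqr, 0)
    e <- d$lncRNA$ecdf
    xs <- seq(-6, 6, by = 0.5)
    expect_true(all(diff(e(xs)) >= 0))
    expect_true(all(e(xs) >= 0 & e(xs) <= 1))
    expect_equal(e(10), 1)
  })
})

test_that("housekeeping selection requires ubiquitous stable expression", {
  md <- two_line_metadata()
  f <- matrix(10, 3, 8, dimnames = list(c("hk", "gap", "wild"), md$sample_id))
  f["gap", 3] <- 0
  f["wild", ] <- c(1, 30, 2, 40, 1, 25, 3, 50)
  sel <- select_housekeeping(f)
  expect_equal(sel, "hk")
  expect_warning(select_housekeeping(f[2:3, , drop = FALSE]), "housekeeping")
  # planted housekeeping genes are recovered from the generator
  cfg <- sim_config(seed = 33, n_coding = 80, n_lnc = 20, frac_housekeeping = 0.1)
  ann <- generate_annotation(cfg)$annotation
  ex <- generate_expression(cfg, ann, generate_samples(cfg))
  hk <- select_housekeeping(ex$fpkm)
  expect_true(all(ex$truth$gene_id[ex$truth$housekeeping] %in% hk))
})
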