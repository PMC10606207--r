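test_that("planted two-block structure is recovered with Rand index 1", {
  bl <- make_block_expr(40, 40)
  mods <- detect_modules(bl$expr, min_module_size = 30)
  assigned <- mods$modules
  expect_equal(sum(names(mods$sizes) != "grey"), 2L)
  expect_equal(rand_index(assigned, bl$truth), 1)
})

test_that("independent genes stay unassigned and detection is permutation-invariant", {
  withr::with_seed(92, {
    m <- matrix(rnorm(60 * 40), 60, dimnames = list(sprintf("g%02d", 1:60),
                                                    sprintf("s%02d", 1:40)))
    mods <- detect_modules(m, min_module_size = 30)
    expect_true(all(mods$modules == "grey"))
  })
  bl <- make_block_expr(35, 35, n_noise = 10)
  m1 <- detect_modules(bl$expr, min_module_size = 30)
  perm <- withr::with_seed(93, sample(nrow(bl$expr)))
  m2 <- detect_modules(bl$expr[perm, ], min_module_size = 30)
  expect_identical(m1$modules[rownames(bl$expr)], m2$modules[rownames(bl$expr)])
  # constant gene dropped with warning
  bad <- rbind(bl$expr, const = rep(1, ncol(bl$expr)))
  expect_warning(detect_modules(bad, min_module_size = 30), "constant")
})

test_that("eigengene is the first PC with the sign convention and PC1 optimality", {
  # module of identical profiles: eigengene proportional, every MM = 1
  prof <- sin(seq_len(30))
  m <- matrix(rep(prof, each = 5), 5, byrow = FALSE) +
    0   # 5 identical genes x 30 samples
  m <- t(vapply(1:5, function(i) prof, numeric(30)))
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:30))
  eg <- eigengene(m)
  expect_true(all(abs(eg$mm - 1) < 1e-12))
  expect_gt(cor(eg$score, prof), 0.999)
  expect_equal(sd(eg$score), 1, tolerance = 1e-12)

  # planted one-factor module with loading 0.8 -> mean MM near 0.8
  withr::with_seed(94, {
    f <- rnorm(60)
    mm <- t(vapply(1:50, function(i) 0.8 * f + 0.6 * rnorm(60), numeric(60)))
    dimnames(mm) <- list(paste0("g", 1:50), paste0("s", 1:60))
    eg2 <- eigengene(mm)
    expect_gte(mean(eg2$mm), 0)   # sign convention
    expect_lt(abs(mean(eg2$mm) - 0.8), 0.1)
    # PC1 optimality: no single gene's profile explains more total squared
    # correlation than the eigengene does
    for (i in c(1, 25, 50))
      expect_gte(sum(eg2$mm^2) + 1e-9,
                 sum(as.numeric(cor(t(mm), mm[i, ]))^2))
  })
  expect_error(eigengene(mm[1, , drop = FALSE]), ">= 2")
})

test_that("module-trait correlations retain driven modules and behave under nulls", {
  bl <- make_block_expr(40, 40, n_samp = 50)
  mods <- detect_modules(bl$expr, min_module_size = 30)
  eg <- mods$eigengenes
  # trait equal to an eigengene correlates perfectly
  traits <- data.frame(t1 = eg[, 1], t2 = rnorm(nrow(eg)))
  mt <- module_trait(mods, traits)
  expect_equal(unname(mt$r[colnames(eg)[1], "t1"]), 1, tolerance = 1e-9)
  expect_true(any(mt$retained$module == colnames(eg)[1] &
                    mt$retained$trait == "t1"))
  # constant trait skipped with warning, others still correlated
  expect_warning(mt3 <- module_trait(mods, data.frame(flat = rep(1, nrow(eg)),
                                                      ok = traits$t2)),
                 "constant")
  expect_false("flat" %in% colnames(mt3$r))
  expect_true("ok" %in% colnames(mt3$r))

  # planted driver: trait = 0.6 * eigengene + noise, retained in most seeds
  hit <- vapply(1:20, function(sd) withr::with_seed(200 + sd, {
    tr <- data.frame(drv = 0.6 * eg[, 1] + sqrt(1 - 0.36) * rnorm(nrow(eg)))
    mt2 <- module_trait(mods, tr)
    any(mt2$retained$module == colnames(eg)[1])
  }), logical(1))
  expect_gte(mean(hit), 0.9)
  # shuffled trait: retention at the nominal error rate
  null_hits <- vapply(1:40, function(sd) withr::with_seed(300 + sd, {
    tr <- data.frame(shuf = sample(eg[, 1]))
    nrow(module_trait(mods, tr)$retained) > 0
  }), logical(1))
  expect_lte(mean(null_hits), 0.15)
})

test_that("MM-GS correlation is exact for eigengene traits and sign-covariant", {
  bl <- make_block_expr(40, 10, n_samp = 50)
  m <- bl$expr[bl$truth == "b1", ]
  eg <- eigengene(m)
  r <- mm_gs(m, eg$score)
  expect_equal(r$cor_mm_gs, 1, tolerance = 1e-6)
  expect_true(r$flag)
  r_neg <- mm_gs(m, -eg$score)
  expect_equal(r_neg$cor_mm_gs, -r$cor_mm_gs, tolerance = 1e-9)
  expect_error(mm_gs(m[1:2, ], eg$score), "size")
  # random trait: flag off in most seeds
  off <- vapply(1:20, function(sd) withr::with_seed(400 + sd, {
    !mm_gs(m, rnorm(ncol(m)))$flag
  }), logical(1))
  expect_gte(mean(off), 0.9)
})

test_that("ceRNA assembly emits exactly the miRNA-bridged triples", {
  lnc <- data.frame(rna_id = "lncA", rna_type = "lncRNA", mirna_id = "miR1",
                    interaction = "cleavage", stringsAsFactors = FALSE)
  mrna <- data.frame(rna_id = "mA", rna_type = "mRNA", mirna_id = "miR1",
                     interaction = "translation_inhibition", stringsAsFactors = FALSE)
  circ0 <- lnc[0, ]
  net <- build_cerna(lnc, circ0, mrna)
  expect_equal(nrow(net$bridges), 1L)
  expect_equal(net$bridges$mirna_id, "miR1")

  # disjoint miRNA namespaces -> no bridges
  mrna2 <- transform(mrna, mirna_id = "miR9")
  expect_equal(nrow(build_cerna(lnc, circ0, mrna2)$bridges), 0L)

  expect_error(build_cerna(transform(lnc, interaction = "sponge"), circ0, mrna),
               "unknown interaction")
})

test_that("planted bridges among distractors match a brute-force join oracle", {
  cfg <- sim_config(seed = 95, n_bridges = 10, n_distractors = 100)
  mi <- generate_mirna_targets(cfg)
  net <- build_cerna(mi$lnc_mir, mi$circ_mir, mi$mrna_mir)
  expect_equal(nrow(net$bridges), 10L)
  got <- with(net$bridges, sort(paste(ncrna_id, mirna_id, mrna_id)))
  want <- with(mi$truth, sort(paste(ncrna_id, mirna_id, mrna_id)))
  expect_identical(got, want)

  # brute-force join oracle over all edge pairs
  nc <- rbind(mi$lnc_mir, mi$circ_mir)
  brute <- character(0)
  for (i in seq_len(nrow(nc))) for (j in seq_len(nrow(mi$mrna_mir)))
    if (nc$mirna_id[i] == mi$mrna_mir$mirna_id[j])
      brute <- c(brute, paste(nc$rna_id[i], nc$mirna_id[i], mi$mrna_mir$rna_id[j]))
  expect_identical(got, sort(unique(brute)))

  # independence of table concatenation order
  net2 <- build_cerna(mi$lnc_mir[rev(seq_len(nrow(mi$lnc_mir))), ],
                      mi$circ_mir, mi$mrna_mir)
  expect_identical(net$bridges, net2$bridges)
})

test_that("network statistics equal brute-force set cardinalities", {
  cfg <- sim_config(seed = 96, n_bridges = 5, n_distractors = 40)
  mi <- generate_mirna_targets(cfg)
  edges <- rbind(mi$lnc_mir, mi$circ_mir, mi$mrna_mir)
  st <- network_stats(edges)
  expect_equal(st$n_lncRNA, length(unique(edges$rna_id[edges$rna_type == "lncRNA"])))
  expect_equal(st$n_miRNA, length(unique(edges$mirna_id)))
  expect_equal(st$n_edges, nrow(unique(edges[, c("rna_id", "mirna_id")])))
  st2 <- network_stats(edges[rev(seq_len(nrow(edges))), ])
  expect_equal(st2$n_edges, st$n_edges)
  one <- network_stats(edges[1, , drop = FALSE])
  expect_equal(one$n_lncRNA + one$n_circRNA + one$n_mRNA, 1L)
  expect_error(network_stats(edges[0, ]), "non-empty")
})
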