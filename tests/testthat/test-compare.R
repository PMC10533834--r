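test_that("knn_graph matches brute force and breaks ties by index", {
  # collinear equally spaced cells: the middle cell's neighbors are the ends
  sc <- cbind(c(0, 1, 2), 0)
  g <- knn_graph(sc, k = 2)
  expect_setequal(g$index[2, ], c(1L, 3L))
  set.seed(21)
  x <- matrix(rnorm(50 * 4), 50, 4)
  g50 <- knn_graph(x, k = 7)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  for (i in 1:50)
    expect_setequal(g50$index[i, ], order(d[i, ])[1:7])
  # duplicated coordinates resolve to the lower index, deterministically
  dup <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 5))
  gd <- knn_graph(dup, k = 1)
  expect_equal(gd$index[, 1], c(2L, 1L, 1L, 1L))
  expect_error(knn_graph(sc, k = 3), "more cells than k")
})

test_that("composition distance follows the cosine formula", {
  # 6 cells, two genotypes; a cell with 2 same-genotype neighbors under a
  # balanced expectation sits at 1 - 1/sqrt(2)
  sc <- cbind(c(0, 0.1, 0.2, 10, 10.1, 10.2), 0)
  geno <- c("A", "A", "A", "B", "B", "B")
  g <- knn_graph(sc, k = 2)
  cz <- composition_zscores(g, geno, n_permutations = 50, seed = 1)
  expect_equal(cz$observed_distance[1], 1 - 1 / sqrt(2), tolerance = 1e-12)
  # a neighborhood matching the global composition has distance 0:
  # cell 2's neighbors are cells 1 (A) and 3 (B), matching the 50/50 global
  sc2 <- cbind(seq(0, 0.5, length.out = 6), 0)
  g2 <- knn_graph(sc2, k = 2)
  geno2 <- c("A", "A", "B", "B", "A", "B")
  cz2 <- composition_zscores(g2, geno2, n_permutations = 50, seed = 1)
  expect_equal(cz2$observed_distance[2], 0, tolerance = 1e-12)
  expect_error(composition_zscores(g, rep("A", 6), 10), "degenerate")
})

test_that("permuted labels give z-scores centered at zero", {
  cfg <- small_config(seed = 22, n_cells_per_genotype = 250)
  ds <- generate_counts(cfg)
  emb <- pca_embed(normalize_log(ds), select_hvgs(ds$counts, 200), n_pcs = 8)
  g <- knn_graph(emb, k = 19)
  set.seed(99)
  cz <- composition_zscores(g, sample(ds$genotype), n_permutations = 200,
                            seed = 5)
  expect_lt(abs(mean(cz$z, na.rm = TRUE)), 0.1)
  expect_equal(cz$z, (cz$observed_distance - cz$null_mean) / cz$null_sd)
})

test_that("pc_alignment is exact on identity and sign-invariant", {
  set.seed(23)
  load <- qr.Q(qr(matrix(rnorm(200 * 10), 200, 10)))
  rownames(load) <- sprintf("g%03d", 1:200)
  al <- pc_alignment(load, load, n_pcs = 10)
  expect_equal(unname(al$best_match), rep(1, 10), tolerance = 1e-12)
  flipped <- load %*% diag(c(-1, 1, -1, rep(1, 7)))
  dimnames(flipped) <- dimnames(load)
  al2 <- pc_alignment(load, flipped, n_pcs = 10)
  expect_equal(al$best_match, al2$best_match, tolerance = 1e-12)
  # sign flips leave the whole |similarity| matrix unchanged
  expect_equal(abs(al$similarity), abs(al2$similarity), tolerance = 1e-12)
  # random orthogonal loadings in a 1000-gene space barely align
  for (s in 1:3) {
    set.seed(s)
    a <- qr.Q(qr(matrix(rnorm(1000 * 10), 1000, 10)))
    b <- qr.Q(qr(matrix(rnorm(1000 * 10), 1000, 10)))
    rownames(a) <- rownames(b) <- sprintf("g%04d", 1:1000)
    expect_lt(max(pc_alignment(a, b, n_pcs = 10)$best_match), 0.2)
  }
  expect_error(pc_alignment(load[1:5, ], load[6:10, ]), "shared genes")
})

test_that("pc_null_by_split returns the pooled null at the right size", {
  cfg <- small_config(seed = 24, genotype_labels = "wt",
                      n_cells_per_genotype = 200)
  ds <- generate_counts(cfg)
  null <- pc_null_by_split(ds, 0.5, n_repeats = 3, n_pcs = 5, n_hvgs = 100,
                           seed = 1)
  expect_length(null, 3 * 5)
  expect_true(all(null >= 0 & null <= 1))
  expect_error(pc_null_by_split(ds, 0.02, n_pcs = 5), "fewer cells")
})

test_that("alteration_test is null on shuffled labels and flags the shift", {
  cfg <- small_config(seed = 25, n_cells_per_genotype = 300,
                      genotype_labels = c("unrelated_wt", "mutant"))
  ds <- generate_counts(cfg)
  norm <- normalize_log(ds)
  markers <- data.frame(cluster = rep(1:3, each = 10),
                        gene = unlist(ds$marker_genes))
  # identical expression, random genotypes: never significant over 5 seeds
  for (s in 1:5) {
    set.seed(s)
    at <- alteration_test(norm, ds$true_cluster, sample(ds$genotype),
                          markers, wt = "unrelated_wt", mut = "mutant")
    expect_true(all(at$bonferroni_p >= 0.05))
    expect_lt(max(abs(at$median_all_ratio - 1)), 0.2)
  }
  # doubling cluster 2's markers in the mutant is detected in cluster 2
  norm2 <- norm
  mut2 <- ds$genotype == "mutant" & ds$true_cluster == 2
  norm2[ds$marker_genes[[2]], mut2] <- norm2[ds$marker_genes[[2]], mut2] * 2
  at2 <- alteration_test(norm2, ds$true_cluster, ds$genotype, markers,
                         wt = "unrelated_wt", mut = "mutant")
  expect_equal(at2$cluster[which.min(at2$bonferroni_p)], 2)
  expect_lt(at2$bonferroni_p[at2$cluster == 2], 0.05)
  expect_equal(at2$bonferroni_p, pmin(1, at2$raw_p * nrow(at2)))
  # markers identical to the comparison set: maximal p
  all_mk <- data.frame(cluster = 1, gene = rownames(norm))
  at3 <- alteration_test(norm, rep(1, ncol(norm)), ds$genotype, all_mk,
                         wt = "unrelated_wt", mut = "mutant",
                         detected_min_frac = 0)
  expect_gt(at3$raw_p, 0.9)
})

test_that("global DE filter applies the printed thresholds", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    log2fc = c(1.2, 3, 0.3, 0.3, -1.5, 0.2),
                    adjusted_p = c(0.01, 0.2, 0.01, 0.01, 0.03, 0.04),
                    pct_a = c(0.5, 0.5, 0.50, 0.30, 0.4, 0.2),
                    pct_b = c(0.5, 0.5, 0.20, 0.35, 0.4, 0.0))
  out <- global_de_filter(tab)
  expect_false("g2" %in% out$gene)                  # fails adjusted p
  expect_true(out$highlighted[out$gene == "g1"])    # |lfc| > 1
  expect_true(out$highlighted[out$gene == "g3"])    # pct ratio 2.5
  expect_false(out$highlighted[out$gene == "g4"])   # nothing crosses
  expect_true(out$highlighted[out$gene == "g5"])    # lfc < -1
  expect_true(out$highlighted[out$gene == "g6"])    # ratio infinite
  expect_true(out$pct_ratio_infinite[out$gene == "g6"])
})

test_that("marker persistence splits transient from sustained", {
  norm <- matrix(0, 1, 300, dimnames = list("gx", NULL))
  lab <- rep(1:3, each = 100)
  norm[1, lab == 1] <- rep(c(1, 0), c(60, 40))
  expect_equal(marker_persistence(norm, lab, 1, "gx"), "transient")
  norm[1, lab == 2] <- rep(c(1, 0), c(30, 70))
  expect_equal(marker_persistence(norm, lab, 1, "gx"), "sustained")
  norm[1, lab == 2] <- rep(c(1, 0), c(10, 90))   # exactly at the threshold
  expect_equal(marker_persistence(norm, lab, 1, "gx"), "sustained")
  expect_error(marker_persistence(norm, lab, 1, "nope"), "absent")
})

test_that("proportion test reproduces the exact rank-sum tail", {
  # 4 vs 4 experiments, complete separation in cluster 1
  lab <- c(rep(1, 40), rep(2, 60))
  # experiment-level fractions of cluster 1: wt > mut in every experiment
  mk_unit <- function(geno, exper, f1, n = 50) {
    data.frame(lab = rep(1:2, c(round(n * f1), n - round(n * f1))),
               geno = geno, exper = exper)
  }
  units <- rbind(mk_unit("wt", "e1", 0.50), mk_unit("wt", "e2", 0.52),
                 mk_unit("wt", "e3", 0.54), mk_unit("wt", "e4", 0.56),
                 mk_unit("mut", "e1", 0.30), mk_unit("mut", "e2", 0.32),
                 mk_unit("mut", "e3", 0.34), mk_unit("mut", "e4", 0.36))
  pt <- proportion_test(units$lab, units$geno, units$exper,
                        group_a = "wt", group_b = "mut")
  expect_equal(pt$tests$raw_p[1], 2 / choose(8, 4), tolerance = 1e-10)
  expect_equal(pt$tests$raw_p[1], 0.02857, tolerance = 1e-3)
  # fractions sum to one within each (genotype, experiment)
  sums <- tapply(pt$fractions$fraction,
                 paste(pt$fractions$genotype, pt$fractions$experiment),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # identical fractions in every experiment: maximal p
  same <- rbind(mk_unit("wt", "e1", 0.4), mk_unit("wt", "e2", 0.4),
                mk_unit("mut", "e1", 0.4), mk_unit("mut", "e2", 0.4))
  pt2 <- proportion_test(same$lab, same$geno, same$exper,
                         group_a = "wt", group_b = "mut")
  expect_true(all(pt2$tests$raw_p == 1))
  expect_error(proportion_test(units$lab[1:100],
                               rep(c("wt", "mut"), c(50, 50)),
                               rep("e1", 100), "wt", "mut"),
               ">= 2 experiments")
})

test_that("composition ratios reproduce the reported roundings", {
  expect_equal(composition_ratio(82.6, 4.4)$rounded, 19)
  expect_equal(composition_ratio(73.5, 7.9)$rounded, 9)
  expect_equal(composition_ratio(50, 50)$rounded, 1)
  expect_equal(composition_ratio(82.6, 4.4)$ratio *
                 composition_ratio(4.4, 82.6)$ratio, 1, tolerance = 1e-12)
  expect_error(composition_ratio(10, 0), "zero")
})

test_that("enrichment chi-squared is the uncorrected Pearson statistic", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- enrichment_chisq(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  tab <- matrix(c(15234, 811, 12516, 1345), 2)
  res2 <- enrichment_chisq(tab)
  expect_lt(res2$p_value, 2.2e-16)
  swapped <- tab[2:1, ]
  expect_equal(enrichment_chisq(swapped)$statistic, res2$statistic)
  expect_error(enrichment_chisq(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
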