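make_qc_dataset <- function() {
  # 5 genes (1 mito) x 4 hand-built cells
  counts <- matrix(0L, 5, 4,
                   dimnames = list(c("mt-g1", "g2", "g3", "g4", "g5"),
                                   paste0("c", 1:4)))
  # c1: fine; c2: too few detected genes; c3: exactly 12% mito;
  # c4: too many UMIs
  counts[, 1] <- c(10L, 200L, 300L, 200L, 290L)
  counts[2, 2] <- 450L
  counts[, 3] <- c(120L, 300L, 300L, 160L, 120L)
  counts[, 4] <- c(100L, 3000L, 3000L, 2000L, 900L)
  count_dataset(counts, mito_flags = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                genotype = rep("wt", 4), replicate = rep("e1", 4))
}

test_that("qc_filter applies inclusive bounds per criterion", {
  ds <- make_qc_dataset()
  thr <- qc_thresholds(min_genes = 3, max_genes = 4000, min_umis = 400,
                       max_umis = 8000, max_mito_frac = 0.12)
  res <- qc_filter(ds, thr)
  expect_identical(res$dataset$cell_ids, c("c1", "c3"))
  expect_false(res$report$pass_genes[2])   # 1 detected gene < min
  expect_false(res$report$pass_umis[4])    # 9000 UMIs > max
  expect_equal(res$report$mito_frac[3], 0.12)
  expect_true(res$report$pass_mito[3])     # boundary retained
  # idempotence
  res2 <- qc_filter(res$dataset, thr)
  expect_identical(res2$dataset$cell_ids, res$dataset$cell_ids)
  # a cell with 150 detected genes is removed under the study thresholds
  big <- matrix(0L, 300, 2,
                dimnames = list(sprintf("g%03d", 1:300), c("a", "b")))
  big[1:150, 1] <- 4L
  big[1:250, 2] <- 4L
  ds2 <- count_dataset(big, mito_flags = rep(FALSE, 300),
                       genotype = c("wt", "wt"), replicate = c("e", "e"))
  out <- qc_filter(ds2, qc_thresholds())
  expect_identical(out$dataset$cell_ids, "b")
  expect_error(qc_filter(ds, qc_thresholds(min_genes = 3000,
                                           max_genes = 4000)),
               "no cells survive")
})

test_that("normalize_log scales to the fixed library size then log1p", {
  counts <- matrix(c(10L, 9990L, 0L,
                     20L, 19980L, 0L), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  norm <- normalize_log(counts)
  expect_equal(norm["g1", "c1"], log(1 + 10))      # library already 10,000
  expect_equal(norm[, "c1"], norm[, "c2"])         # scale invariance
  expect_true(all(norm["g3", ] == 0))              # all-zero gene stays zero
  expect_equal(unname(colSums(expm1(norm))), c(1e4, 1e4))
  counts[, 2] <- 0L
  expect_error(normalize_log(counts), "zero total")
})

test_that("select_hvgs ranks by standardized variance with stated ties", {
  set.seed(11)
  n <- 500
  counts <- matrix(rpois(80 * n, 5), 80, n,
                   dimnames = list(sprintf("g%02d", 1:80), NULL))
  # one clearly overdispersed gene must rank first
  counts["g40", ] <- rnbinom(n, size = 0.3, mu = 5)
  hv <- select_hvgs(counts, n = 10)
  expect_equal(hv[1], "g40")
  expect_error(select_hvgs(counts, n = 100), "exceeds")
  # exact ties broken lexicographically: duplicated count rows tie exactly
  counts2 <- counts
  counts2["g10", ] <- counts2["g40", ]
  rownames(counts2)[c(10, 40)] <- c("aaa", "zzz")
  hv2 <- select_hvgs(counts2, n = 2)
  expect_identical(hv2, c("aaa", "zzz"))
})

test_that("pca_embed matches an eigendecomposition oracle", {
  set.seed(12)
  x <- matrix(rnorm(10 * 10), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  emb <- pca_embed(x, n_pcs = 5)
  xs <- t(scale(t(x)))
  ev <- eigen(stats::cov(t(xs)))
  for (j in 1:5) {
    v <- ev$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_lt(max(abs(emb$loadings[, j] - v)), 1e-8)
  }
  expect_equal(emb$explained_variance, ev$values[1:5], tolerance = 1e-10)
  expect_true(all(diff(emb$explained_variance) <= 1e-10))
  expect_equal(unname(sqrt(colSums(emb$loadings^2))), rep(1, 5),
               tolerance = 1e-8)
  # sign convention: re-running gives identical, not flipped, loadings
  emb2 <- pca_embed(x, n_pcs = 5)
  expect_identical(emb$loadings, emb2$loadings)
  expect_true(all(apply(emb$loadings, 2,
                        function(u) u[which.max(abs(u))] > 0)))
  # rank-1 data: PC1 explains essentially everything
  r1 <- outer(rnorm(10), rnorm(20))
  dimnames(r1) <- list(paste0("g", 1:10), paste0("c", 1:20))
  e1 <- pca_embed(r1 + 1e-8 * matrix(rnorm(200), 10), n_pcs = 3)
  expect_gt(e1$explained_variance[1] / sum(e1$explained_variance), 0.999)
  expect_error(pca_embed(x, n_pcs = 50), "n_pcs")
})

test_that("clustering recovers separable clusters and scales with resolution", {
  skip_if_not_installed("mclust")
  cfg <- separable_config(seed = 1)
  ds <- generate_counts(cfg)
  emb <- pca_embed(normalize_log(ds), select_hvgs(ds$counts, 300), n_pcs = 10)
  lab <- cluster_cells(emb, resolution = 1, seed = 1)
  expect_equal(mclust::adjustedRandIndex(lab$label, ds$true_cluster), 1.0)
  ks <- vapply(c(0.4, 1.0, 1.8), function(r)
    length(unique(cluster_cells(emb, resolution = r, seed = 1)$label)),
    numeric(1))
  expect_true(all(diff(ks) >= 0))
  # a single homogeneous blob stays one cluster at low resolution
  set.seed(2)
  blob <- matrix(rnorm(300 * 5), 300, 5)
  lab1 <- cluster_cells(structure(list(scores = blob), class = "embedding"),
                        resolution = 0.1, seed = 1)
  expect_equal(length(unique(lab1$label)), 1)
  expect_error(cluster_cells(structure(list(scores = blob[1:10, ]),
                                       class = "embedding"), k_graph = 20),
               "k_graph")
})

test_that("find_markers applies the fold-change, pct and Bonferroni rules", {
  set.seed(13)
  n <- 400
  lab <- rep(1:2, each = n / 2)
  norm <- matrix(abs(rnorm(60 * n, 1, 0.2)), 60, n,
                 dimnames = list(sprintf("g%02d", 1:60), NULL))
  norm["g05", lab == 1] <- norm["g05", lab == 1] + 2    # strong marker
  norm["g06", lab == 1] <- norm["g06", lab == 1] + 0.35 # logfc ~0.5: out
  tab <- find_markers(norm, lab)
  g5 <- tab[tab$gene == "g05" & tab$cluster == 1, ]
  expect_equal(nrow(g5), 1)
  expect_lt(g5$adjusted_p, 0.05)
  expect_gte(g5$avg_log2fc, 0.75)
  expect_false("g06" %in% tab$gene[tab$cluster == 1])
  expect_true(all(tab$adjusted_p >= tab$raw_p))
  # Bonferroni arithmetic is over all genes in the matrix
  expect_equal(g5$adjusted_p, min(1, g5$raw_p * 60))
  expect_error(find_markers(norm, rep(1, n)), "2 clusters")
})

test_that("clustering plus marker finding recovers injected markers", {
  cfg <- separable_config(seed = 3, marker_log2fc = 2,
                          n_cells_per_genotype = 300)
  ds <- generate_counts(cfg)   # >= 300 cells per cluster at 900 cells total
  norm <- normalize_log(ds)
  emb <- pca_embed(norm, select_hvgs(ds$counts, 300), n_pcs = 10)
  lab <- cluster_cells(emb, resolution = 1, seed = 1)
  tab <- find_markers(norm, lab$label)
  # map each true cluster to its majority detected label
  for (k in 1:3) {
    lk <- as.integer(names(which.max(table(lab$label[ds$true_cluster == k]))))
    found <- tab$gene[tab$cluster == lk]
    expect_gte(mean(ds$marker_genes[[k]] %in% found), 0.9)
  }
})
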