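test_that("count generation is deterministic and respects the config", {
  cfg <- small_config(seed = 7)
  ds1 <- generate_counts(cfg)
  ds2 <- generate_counts(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$true_cluster, ds2$true_cluster)
  expect_equal(ncol(ds1$counts), 3 * 150)
  expect_true(all(ds1$counts >= 0))
  expect_true(all(ds1$counts == round(ds1$counts)))
  expect_setequal(unique(ds1$genotype),
                  c("unrelated_wt", "sibling_wt", "mutant"))
  expect_equal(length(unique(ds1$replicate)), 3 * 2)
  expect_true(all(startsWith(ds1$gene_ids[ds1$mito_flags], "mt-")))
})

test_that("a gene's empirical mean matches its NB mean at large n", {
  cfg <- synth_config(n_genes = 50, n_cells_per_genotype = 10000,
                      genotype_labels = "wt", n_clusters = 1,
                      cluster_proportions = 1, n_markers_per_cluster = 0,
                      baseline_mean = 5, baseline_log2_sd = 0,
                      replicate_log2_sd = 0, mito_gene_fraction = 0,
                      include_cycle_genes = FALSE, seed = 2)
  ds <- generate_counts(cfg)
  expect_lt(abs(mean(rowMeans(ds$counts)) - 5) / 5, 0.02)
  expect_lt(max(abs(rowMeans(ds$counts) - 5) / 5), 0.05)
})

test_that("with no effect, per-gene means are balanced across genotypes", {
  cfg <- small_config(seed = 3, n_cells_per_genotype = 2000,
                      replicate_log2_sd = 0)
  ds <- generate_counts(cfg)
  a <- rowMeans(ds$counts[, ds$genotype == "unrelated_wt"])
  b <- rowMeans(ds$counts[, ds$genotype == "mutant"])
  keep <- a > 0 & b > 0
  expect_lt(abs(median(log2(a[keep] / b[keep]))), 0.05)
})

test_that("ablation removes exactly the targeted cells", {
  cfg <- small_config(seed = 4, effect = effect_ablate(3, "mutant"))
  ds <- generate_counts(cfg)
  expect_equal(sum(ds$true_cluster == 3 & ds$genotype == "mutant"), 0)
  expect_gt(sum(ds$true_cluster == 3 & ds$genotype == "unrelated_wt"), 0)
})

test_that("ablating a nonexistent cluster or genotype errors", {
  expect_error(small_config(effect = effect_ablate(9, "mutant")),
               "cluster")
  expect_error(small_config(effect = effect_ablate(1, "nosuch")),
               "genotype")
  expect_error(synth_config(n_clusters = 0), "n_clusters")
})

test_that("configured marker elevation is recovered from the counts", {
  cfg <- synth_config(n_genes = 800, n_cells_per_genotype = 1100,
                      genotype_labels = "wt", n_clusters = 2,
                      cluster_proportions = c(0.5, 0.5),
                      n_markers_per_cluster = 10, marker_log2fc = 2,
                      seed = 5)
  ds <- generate_counts(cfg)
  in1 <- ds$true_cluster == 1
  expect_gte(sum(in1), 500)
  mk <- ds$marker_genes[[1]]
  recovered <- log2(rowMeans(ds$counts[mk, in1]) /
                      rowMeans(ds$counts[mk, !in1]))
  expect_lt(abs(mean(recovered) - 2), 0.1)
})

test_that("proportion_shift changes the realized fraction accordingly", {
  cfg <- small_config(seed = 6, n_cells_per_genotype = 3000,
                      effect = effect_proportion_shift(1, "mutant", 0.5))
  ds <- generate_counts(cfg)
  f_wt <- mean(ds$true_cluster[ds$genotype == "unrelated_wt"] == 1)
  f_mut <- mean(ds$true_cluster[ds$genotype == "mutant"] == 1)
  # prior 0.4 halved and renormalized: 0.2 / 0.8 = 0.25
  expect_lt(abs(f_wt - 0.4), 0.03)
  expect_lt(abs(f_mut - 0.25), 0.03)
})

test_that("10x triplet round-trips through disk", {
  cfg <- small_config(seed = 8, n_cells_per_genotype = 40, n_genes = 120,
                      include_cycle_genes = FALSE)
  ds <- generate_counts(cfg)
  dir <- withr::local_tempdir()
  write_counts_10x(ds, dir)
  back <- read_counts_10x(dir)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$genotype, ds$genotype)
  expect_identical(back$true_cluster, ds$true_cluster)
  expect_identical(back$mito_flags, ds$mito_flags)
})

test_that("image stacks carry consistent truth and round-trip via TIFF", {
  st0 <- generate_image_stack(n_blobs = 0, seed = 1)
  expect_false(any(st0$true_signal_mask))
  st <- generate_image_stack(spike_slices = 4, seed = 2)
  expect_identical(st$spike_slices_truth, 4L)
  expect_true(all(st$intensities >= 0))
  expect_identical(dim(st$intensities), dim(st$true_signal_mask))
  expect_error(generate_image_stack(signal_level = 10,
                                    background_level = 20),
               "exceed")
  path <- withr::local_tempfile(fileext = ".tiff")
  write_stack_tiff(st$intensities, path)
  expect_equal(read_stack_tiff(path), st$intensities)
})

test_that("eye traces honor the saccade schedule and round-trip via CSV", {
  tr0 <- generate_eye_trace(saccades = NULL, seed = 1)
  expect_equal(nrow(tr0$truth_saccades), 0)
  expect_lt(max(abs(diff(tr0$angle_left))), 5)
  sac <- data.frame(time = c(30, 45, 60, 90, 150),
                    eye = c("left", "left", "left", "left", "left"),
                    direction = rep(1, 5))
  tr <- generate_eye_trace(saccades = sac, seed = 2)
  expect_equal(nrow(tr$truth_saccades), 5)
  expect_true(all(tr$truth_saccades$direction == 1))
  expect_error(generate_eye_trace(
    saccades = data.frame(time = c(10, 10.2), eye = "left",
                          direction = c(1, 1))),
    "refractory")
  path <- withr::local_tempfile(fileext = ".csv")
  write_eye_trace(tr, path)
  back <- read_eye_trace(path)
  expect_equal(back$angle_left, tr$angle_left, tolerance = 1e-6)
  expect_identical(back$phase, tr$phase)
})
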