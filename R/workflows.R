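#' End-to-end genotype-comparison workflow
#'
#' Runs the full chain on a count dataset: QC, normalization, a joint
#' embedding and clustering (no batch correction — the synthetic replicates
#' carry only small offsets, and a shared embedding is required by the
#' neighborhood test), marker finding on the reference genotype,
#' neighborhood composition z-scores, PC alignment of the reference genotype
#' against the mutant with a random-split null, the per-cluster alteration
#' test, cell-type proportion tests, and cell-cycle scoring with phase
#' proportion tests. Per-genotype PCA is computed independently for the
#' alignment stage, mirroring independent processing of each genotype.
#'
#' @param dataset a [count_dataset()].
#' @param wt,mut reference and mutant genotype labels.
#' @param n_hvgs,n_pcs,resolution,k_graph joint pipeline parameters.
#' @param knn_k neighborhood size for the composition test.
#' @param n_permutations label shuffles for the composition null.
#' @param align_pcs,align_hvgs,align_repeats PC-alignment parameters.
#' @param seed integer seed; stage seeds are derived from it and logged in
#'   the manifest.
#' @param out_dir optional directory; results and the JSON manifest are
#'   written as TSVs when given.
#' @return list with `qc_report`, `labels`, `markers`, `composition`,
#'   `pc_alignment`, `alteration`, `proportions`, `cell_cycle`,
#'   `phase_proportions`, `manifest`.
#' @export
run_genotype_comparison <- function(dataset,
                                    wt = "unrelated_wt", mut = "mutant",
                                    n_hvgs = 1000, n_pcs = 14,
                                    resolution = 1, k_graph = 20,
                                    knn_k = 19, n_permutations = 100,
                                    align_pcs = 15, align_hvgs = 1000,
                                    align_repeats = 10,
                                    seed = 1L, out_dir = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  seeds <- list(cluster = seed, composition = seed + 1L,
                split_null = seed + 2L, cell_cycle = seed + 3L)
  qc <- qc_filter(dataset)
  ds <- qc$dataset
  norm <- normalize_log(ds)
  hv <- select_hvgs(ds$counts, n = min(n_hvgs, nrow(ds$counts)))
  emb <- pca_embed(norm, hv, n_pcs = n_pcs)
  lab <- cluster_cells(emb, resolution = resolution, k_graph = k_graph,
                       seed = seeds$cluster)

  wt_cells <- ds$genotype == wt
  markers <- find_markers(norm[, wt_cells, drop = FALSE],
                          lab$label[wt_cells])

  graph <- knn_graph(emb, k = knn_k)
  composition <- composition_zscores(graph, ds$genotype,
                                     n_permutations = n_permutations,
                                     seed = seeds$composition)

  geno_pca <- function(g) {
    sub <- subset_cells(ds, ds$genotype == g)
    nm <- normalize_log(sub)
    hvg <- select_hvgs(sub$counts, n = min(align_hvgs, nrow(sub$counts)))
    pca_embed(nm, hvg, n_pcs = align_pcs)$loadings
  }
  load_wt <- geno_pca(wt)
  load_mut <- geno_pca(mut)
  obs_align <- pc_alignment(load_wt, load_mut, n_pcs = align_pcs)
  n_wt <- sum(ds$genotype == wt)
  n_mut <- sum(ds$genotype == mut)
  null_bm <- pc_null_by_split(subset_cells(ds, wt_cells),
                              split_ratio = n_mut / (n_mut + n_wt),
                              n_repeats = align_repeats, n_pcs = align_pcs,
                              n_hvgs = align_hvgs, seed = seeds$split_null)
  align_p <- pc_alignment_test(obs_align$best_match, null_bm)

  alteration <- alteration_test(norm, lab$label, ds$genotype, markers,
                                wt = wt, mut = mut)
  proportions <- proportion_test(lab$label, ds$genotype, ds$replicate,
                                 group_a = wt, group_b = mut)
  cc <- score_cell_cycle(norm, seed = seeds$cell_cycle)
  phase_props <- phase_proportion_test(cc$phase, ds$genotype, ds$replicate,
                                       group_a = wt, group_b = mut)

  manifest <- list(stage = "genotype_comparison",
                   parameters = list(wt = wt, mut = mut, n_hvgs = n_hvgs,
                                     n_pcs = n_pcs, resolution = resolution,
                                     k_graph = k_graph, knn_k = knn_k,
                                     n_permutations = n_permutations,
                                     align_pcs = align_pcs,
                                     align_hvgs = align_hvgs,
                                     align_repeats = align_repeats),
                   seeds = seeds,
                   n_cells_input = length(dataset$cell_ids),
                   n_cells_qc = length(ds$cell_ids))

  out <- list(qc_report = qc$report, labels = lab, markers = markers,
              composition = composition,
              pc_alignment = c(obs_align,
                               list(null_best_match = null_bm,
                                    p_value = align_p$p_value,
                                    null_q05 = align_p$null_q05)),
              alteration = alteration, proportions = proportions,
              cell_cycle = cc, phase_proportions = phase_props,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wtsv(out$markers, "markers.tsv")
    wtsv(cbind(cell_id = ds$cell_ids, as.data.frame(composition)),
         "composition_z.tsv")
    wtsv(out$alteration, "alteration.tsv")
    wtsv(out$proportions$tests, "proportion_tests.tsv")
    wtsv(out$phase_proportions$tests, "phase_proportion_tests.tsv")
    wtsv(data.frame(cell_id = ds$cell_ids, cluster = lab$label,
                    genotype = ds$genotype, replicate = ds$replicate,
                    s_score = cc$s_score, g2m_score = cc$g2m_score,
                    phase = cc$phase), "cells.tsv")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  out
}

#' End-to-end ablation power analysis
#'
#' Composes the synthetic generator with the ablation detector over a grid of
#' ablated-cluster fractions, plus a null row (no ablation; the rate is the
#' false-positive rate).
#'
#' @param cluster_fractions ablated-cluster fractions for the power grid.
#' @param n_replicates replicates per grid point.
#' @param config base [synth_config()].
#' @param seed integer seed.
#' @param out_dir optional output directory for the TSV report and manifest.
#' @param ... passed to [ablation_replicate()].
#' @return data.frame: one row per fraction plus a `null` row, with
#'   detection_rate (false-positive rate on the null row).
#' @export
run_ablation_power <- function(cluster_fractions = c(0.01, 0.05, 0.10),
                               n_replicates = 20, config = synth_config(),
                               seed = 1L, out_dir = NULL, ...) {
  pw <- power_curve(cluster_fractions, n_replicates = n_replicates,
                    config = config, seed = seed, ...)
  fp <- mean(vapply(seq_len(n_replicates), function(r)
    ablation_replicate(config, cluster = NULL, seed = seed + 900000L + r,
                       ...), logical(1)))
  report <- rbind(cbind(pw, condition = "ablated"),
                  data.frame(cluster_fraction = NA_real_,
                             n_replicates = n_replicates,
                             detection_rate = fp, condition = "null"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "ablation_power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(list(stage = "ablation_power", seed = seed,
                        n_replicates = n_replicates,
                        cluster_fractions = cluster_fractions),
                   file.path(out_dir, "manifest.json"))
  }
  report
}
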