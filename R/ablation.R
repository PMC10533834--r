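#' In-silico cluster ablation and detection power
#'
#' Remove one genotype's cells from one cluster, re-process the truncated
#' matrix blind (no batch correction), and ask whether the missing population
#' is detectable. The original study's visual inspection is replaced by an
#' automated detector: reference cluster identities are transferred by
#' nearest reference-centroid in the re-computed PC space and each reference
#' cluster is tested for mutant depletion with a hypergeometric lower tail.
#'
#' @name ablation
NULL

#' Remove one genotype's cells from one cluster
#'
#' @param dataset a [count_dataset()] with `true_cluster` labels (or pass
#'   `labels`).
#' @param cluster cluster whose cells are removed.
#' @param genotype genotype whose cells are removed.
#' @param labels optional cluster label per cell (defaults to
#'   `dataset$true_cluster`).
#' @return the truncated [count_dataset()]; all other cells and all gene rows
#'   are untouched.
#' @export
ablate_cluster <- function(dataset, cluster, genotype, labels = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (is.null(labels)) labels <- dataset$true_cluster
  if (is.null(labels)) stop("cluster labels required")
  drop <- labels == cluster & dataset$genotype == genotype
  if (!any(drop))
    stop("no cells with (cluster ", cluster, ", genotype ", genotype, ")")
  out <- subset_cells(dataset, !drop)
  out$marker_genes <- dataset$marker_genes
  out
}

#' Re-process a truncated dataset blind
#'
#' Full normalization / HVG / PCA / clustering chain rerun from scratch, with
#' no batch correction (batch correction can mask a missing population).
#'
#' @param dataset a [count_dataset()].
#' @param n_hvgs,n_pcs,resolution,k_graph pipeline parameters.
#' @param seed integer seed (logged in the result).
#' @return list with `embedding`, `labels`, `seed`.
#' @export
reprocess_blind <- function(dataset, n_hvgs = 1000, n_pcs = 14,
                            resolution = 1, k_graph = 20, seed = 1L) {
  norm <- normalize_log(dataset)
  hv <- select_hvgs(dataset$counts, n = min(n_hvgs, nrow(dataset$counts)))
  emb <- pca_embed(norm, hv, n_pcs = n_pcs)
  lab <- cluster_cells(emb, resolution = resolution, k_graph = k_graph,
                       seed = seed)
  list(embedding = emb, labels = lab, seed = seed)
}

#' Detect a missing (depleted) cluster after ablation
#'
#' Reference cluster identities are transferred to every surviving cell by
#' nearest reference-cluster centroid in the re-computed PC space. For each
#' reference cluster the observed mutant count is tested against the
#' hypergeometric expectation under the global mutant fraction (lower tail =
#' depletion). The ablated cluster counts as detected when it ranks first by
#' depletion p, passes the Bonferroni-corrected alpha, and is grossly
#' depleted (observed mutants below `missing_ratio` of expectation): a
#' "missing" population is near-absent, not marginally depleted, and the
#' gate keeps the verdict conservative on null data.
#'
#' @param embedding the re-computed `embedding` of the surviving cells.
#' @param genotypes genotype label per surviving cell.
#' @param reference_labels reference cluster label per surviving cell.
#' @param ablated_cluster the cluster that was ablated (for the `detected`
#'   verdict; `NULL` for a null run).
#' @param mutant_label the genotype tested for depletion.
#' @param alpha nominal level before Bonferroni correction.
#' @param missing_ratio maximum observed/expected mutant ratio for a cluster
#'   to count as missing.
#' @param labels optional re-clustering labels, carried through for
#'   inspection only.
#' @return an `ablation_result` list: `table` (per reference cluster:
#'   n_cells, n_expected_mutant, n_observed_mutant, depletion_p, rank,
#'   testable), `detected`, `ablated_cluster`, `alpha`.
#' @export
detect_missing_cluster <- function(embedding, genotypes, reference_labels,
                                   ablated_cluster = NULL,
                                   mutant_label = "mutant", alpha = 0.05,
                                   missing_ratio = 0.5, labels = NULL) {
  scores <- embedding$scores
  stopifnot(nrow(scores) == length(genotypes),
            length(reference_labels) == length(genotypes))
  ref <- sort(unique(reference_labels))
  centroids <- t(vapply(ref, function(k)
    colMeans(scores[reference_labels == k, , drop = FALSE]),
    numeric(ncol(scores))))
  d2 <- outer(rowSums(scores^2), rowSums(centroids^2), "+") -
    2 * scores %*% t(centroids)
  transferred <- ref[max.col(-d2, ties.method = "first")]
  is_mut <- genotypes == mutant_label
  m <- sum(is_mut)
  n_tot <- length(genotypes)
  tab <- data.frame(cluster = ref, n_cells = NA_integer_,
                    n_expected_mutant = NA_real_,
                    n_observed_mutant = NA_integer_,
                    depletion_p = NA_real_, testable = TRUE)
  for (i in seq_along(ref)) {
    kx <- transferred == ref[i]
    tab$n_cells[i] <- sum(kx)
    if (tab$n_cells[i] == 0) {
      tab$testable[i] <- FALSE
      next
    }
    tab$n_observed_mutant[i] <- sum(kx & is_mut)
    tab$n_expected_mutant[i] <- tab$n_cells[i] * m / n_tot
    tab$depletion_p[i] <- stats::phyper(tab$n_observed_mutant[i], m,
                                        n_tot - m, tab$n_cells[i])
  }
  n_tested <- sum(tab$testable)
  tab$rank <- rank(tab$depletion_p, ties.method = "first",
                   na.last = "keep")
  tab$missing <- tab$testable & !is.na(tab$rank) & tab$rank == 1 &
    tab$depletion_p < alpha / n_tested &
    tab$n_observed_mutant < missing_ratio * tab$n_expected_mutant
  detected <- FALSE
  if (!is.null(ablated_cluster)) {
    row <- which(tab$cluster == ablated_cluster)
    detected <- length(row) == 1 && tab$missing[row]
  }
  structure(list(table = tab, detected = detected,
                 ablated_cluster = ablated_cluster, alpha = alpha,
                 missing_ratio = missing_ratio, n_tested = n_tested),
            class = "ablation_result")
}

#' Run one simulate / ablate / re-process / detect replicate
#'
#' @param config a [synth_config()]; its `effect` is ignored.
#' @param cluster cluster to ablate (`NULL` for a null replicate: nothing is
#'   removed and a "detection" of any cluster counts as a false positive).
#' @param genotype genotype to ablate.
#' @param n_hvgs,n_pcs,resolution,k_graph,alpha pipeline parameters.
#' @param seed integer seed (drives both the simulation and re-processing).
#' @return logical: detected (effect run) or any false positive (null run).
#' @export
ablation_replicate <- function(config, cluster = 1, genotype = "mutant",
                               n_hvgs = 500, n_pcs = 12, resolution = 1,
                               k_graph = 20, alpha = 0.05, seed = 1L) {
  config$seed <- seed
  ds <- generate_counts(config)
  if (!is.null(cluster)) ds <- ablate_cluster(ds, cluster, genotype)
  rp <- reprocess_blind(ds, n_hvgs = n_hvgs, n_pcs = n_pcs,
                        resolution = resolution, k_graph = k_graph,
                        seed = seed)
  res <- detect_missing_cluster(rp$embedding, ds$genotype, ds$true_cluster,
                                ablated_cluster = cluster, alpha = alpha)
  if (!is.null(cluster)) return(res$detected)
  # null: any cluster wrongly flagged as missing is a false positive
  any(res$table$missing)
}

#' Detection power over a grid of ablated-cluster sizes
#'
#' For each cluster fraction, cluster 1's sampling proportion is set to that
#' fraction (remaining mass spread uniformly), the mutant cells of cluster 1
#' are ablated, and the automated detector is run; the detection rate is the
#' fraction of replicates detected. A fraction of 0 means no cells to ablate,
#' so its rate is 0 by construction.
#'
#' @param cluster_fractions numeric vector of ablated-cluster fractions.
#' @param n_replicates replicates per fraction.
#' @param config base [synth_config()]; cluster 1's proportion is overridden.
#' @param seed integer seed; replicate r of fraction i uses a derived seed.
#' @param ... passed to [ablation_replicate()].
#' @return data.frame with cluster_fraction, n_replicates, detection_rate.
#' @export
power_curve <- function(cluster_fractions, n_replicates = 20,
                        config = synth_config(), seed = 1L, ...) {
  stopifnot(length(cluster_fractions) >= 1)
  K <- config$n_clusters
  rates <- numeric(length(cluster_fractions))
  for (i in seq_along(cluster_fractions)) {
    f <- cluster_fractions[i]
    if (f == 0) {
      rates[i] <- 0
      next
    }
    cfg <- config
    cfg$cluster_proportions <- c(f, rep((1 - f) / (K - 1), K - 1))
    hits <- vapply(seq_len(n_replicates), function(r)
      ablation_replicate(cfg, cluster = 1, seed = seed + 1000L * i + r, ...),
      logical(1))
    rates[i] <- mean(hits)
  }
  data.frame(cluster_fraction = cluster_fractions,
             n_replicates = n_replicates, detection_rate = rates)
}
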