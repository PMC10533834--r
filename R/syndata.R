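#' Synthetic study-design generators
#'
#' Generators that emulate the statistical structure of a three-genotype
#' (unrelated WT / sibling WT / mutant) single-cell RNA-seq study of the
#' larval zebrafish visual brain, plus matched image-stack and eye-trace
#' fixtures. Counts are negative binomial with cluster-specific marker
#' elevation; optional effects inject the alternatives the comparison
#' statistics are meant to detect (cluster ablation, marker dysregulation,
#' proportion shifts, a cell-cycle continuum).
#'
#' @name syndata
NULL

#' Effect descriptors for the count generator
#'
#' @param cluster integer cluster index the effect applies to.
#' @param genotype genotype label the effect applies to.
#' @param factor multiplicative change of the cluster's sampling proportion.
#' @param genes character vector of gene ids to dysregulate; `NULL` means the
#'   cluster's own marker genes.
#' @param log2fc log2 fold change applied to the dysregulated genes.
#' @param phase_fractions named fractions for G1/S/G2M within the cluster.
#' @param phase_factor multiplicative elevation of S (resp. G2M) gene means in
#'   S (resp. G2M) cells.
#' @return A list of class `synth_effect` describing the effect.
#' @export
effect_none <- function() {
  structure(list(type = "none"), class = "synth_effect")
}

#' @rdname effect_none
#' @export
effect_ablate <- function(cluster, genotype) {
  structure(list(type = "ablate", cluster = cluster, genotype = genotype),
            class = "synth_effect")
}

#' @rdname effect_none
#' @export
effect_dysregulate <- function(cluster, genes = NULL, log2fc = 2,
                               genotype = "mutant") {
  structure(list(type = "dysregulate", cluster = cluster, genes = genes,
                 log2fc = log2fc, genotype = genotype),
            class = "synth_effect")
}

#' @rdname effect_none
#' @export
effect_proportion_shift <- function(cluster, genotype, factor) {
  stopifnot(factor >= 0)
  structure(list(type = "proportion_shift", cluster = cluster,
                 genotype = genotype, factor = factor),
            class = "synth_effect")
}

#' @rdname effect_none
#' @export
effect_cycle_continuum <- function(cluster,
                                   phase_fractions = c(G1 = 0.5, S = 0.25,
                                                       G2M = 0.25),
                                   phase_factor = 4) {
  stopifnot(abs(sum(phase_fractions) - 1) < 1e-9,
            all(c("G1", "S", "G2M") %in% names(phase_fractions)))
  structure(list(type = "cycle_continuum", cluster = cluster,
                 phase_fractions = phase_fractions,
                 phase_factor = phase_factor),
            class = "synth_effect")
}

#' Configuration for the synthetic count generator
#'
#' Defaults reflect the emulated study design: three genotypes with several
#' replicated experiments each, a moderate number of transcriptomic clusters
#' with a handful of strong positive markers per cluster, and sparse UMI
#' counts (negative binomial, gene-level mean/dispersion).
#'
#' @param n_genes number of genes.
#' @param n_cells_per_genotype cells simulated per genotype (before ablation).
#' @param genotype_labels ordered genotype labels.
#' @param n_replicates_per_genotype replicated experiments per genotype.
#' @param n_clusters number of cell-type clusters K.
#' @param cluster_proportions simplex vector of length K (default uniform).
#' @param n_markers_per_cluster marker genes per cluster.
#' @param marker_log2fc log2 elevation of marker means in their cluster.
#' @param baseline_mean median negative-binomial mean of a non-marker gene;
#'   per-gene means are log-normal around it (see `baseline_log2_sd`).
#' @param baseline_log2_sd sd of the per-gene log2 baseline mean — real UMI
#'   data span orders of magnitude in gene abundance, which HVG selection
#'   and expression-bin-matched control sampling both rely on; set 0 for a
#'   flat baseline.
#' @param dispersion negative-binomial size parameter.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial
#'   (named with the zebrafish "mt-" prefix).
#' @param replicate_log2_sd sd of the per-replicate, per-gene log2 mean
#'   offset; set 0 for identical replicates.
#' @param include_cycle_genes name 102 baseline genes after the zebrafish
#'   S/G2M cell-cycle sets so cycle scoring is exercised on any dataset;
#'   requires enough genes, disable for minimal fixtures.
#' @param effect a [effect_none()]-family descriptor.
#' @param seed integer seed; all randomness derives from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 2000,
                         n_cells_per_genotype = 1000,
                         genotype_labels = c("unrelated_wt", "sibling_wt",
                                             "mutant"),
                         n_replicates_per_genotype = 4,
                         n_clusters = 8,
                         cluster_proportions = NULL,
                         n_markers_per_cluster = 10,
                         marker_log2fc = 2,
                         baseline_mean = 0.5,
                         baseline_log2_sd = 1,
                         dispersion = 2,
                         mito_gene_fraction = 0.02,
                         replicate_log2_sd = 0.05,
                         include_cycle_genes = TRUE,
                         effect = effect_none(),
                         seed = 1L) {
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  stopifnot(n_genes >= 1, n_cells_per_genotype >= 1,
            n_replicates_per_genotype >= 1,
            length(genotype_labels) >= 1,
            !anyDuplicated(genotype_labels))
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have length n_clusters")
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  stopifnot(baseline_mean > 0, baseline_log2_sd >= 0, dispersion > 0,
            marker_log2fc >= 0,
            mito_gene_fraction >= 0, mito_gene_fraction <= 1,
            inherits(effect, "synth_effect"))
  if (effect$type %in% c("ablate", "dysregulate", "proportion_shift",
                         "cycle_continuum")) {
    if (!(effect$cluster %in% seq_len(n_clusters)))
      stop("effect cluster ", effect$cluster, " does not exist (K = ",
           n_clusters, ")")
    if (!is.null(effect$genotype) &&
        !(effect$genotype %in% genotype_labels))
      stop("effect genotype '", effect$genotype, "' does not exist")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_genotype = as.integer(n_cells_per_genotype),
                 genotype_labels = genotype_labels,
                 n_replicates_per_genotype =
                   as.integer(n_replicates_per_genotype),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 n_markers_per_cluster = as.integer(n_markers_per_cluster),
                 marker_log2fc = marker_log2fc,
                 baseline_mean = baseline_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 dispersion = dispersion,
                 mito_gene_fraction = mito_gene_fraction,
                 replicate_log2_sd = replicate_log2_sd,
                 include_cycle_genes = include_cycle_genes,
                 effect = effect,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Construct a count dataset container
#'
#' @param counts genes x cells non-negative integer matrix with dimnames.
#' @param mito_flags logical per gene.
#' @param genotype,replicate labels per cell.
#' @param true_cluster,true_phase optional ground-truth labels per cell.
#' @return A `count_dataset` list.
#' @export
count_dataset <- function(counts, mito_flags, genotype, replicate,
                          true_cluster = NULL, true_phase = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)),
            !anyDuplicated(rownames(counts)),
            !anyDuplicated(colnames(counts)))
  n <- ncol(counts)
  stopifnot(length(mito_flags) == nrow(counts),
            length(genotype) == n, length(replicate) == n)
  if (!is.null(true_cluster)) stopifnot(length(true_cluster) == n)
  if (!is.null(true_phase)) stopifnot(length(true_phase) == n)
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 mito_flags = mito_flags,
                 cell_ids = colnames(counts),
                 genotype = as.character(genotype),
                 replicate = as.character(replicate),
                 true_cluster = true_cluster,
                 true_phase = true_phase),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("genotypes:", paste(names(table(x$genotype)), table(x$genotype),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count dataset by cells
#'
#' @param dataset a `count_dataset`.
#' @param keep logical or integer index over cells.
#' @return The subsetted `count_dataset`.
#' @export
subset_cells <- function(dataset, keep) {
  count_dataset(dataset$counts[, keep, drop = FALSE],
                mito_flags = dataset$mito_flags,
                genotype = dataset$genotype[keep],
                replicate = dataset$replicate[keep],
                true_cluster = dataset$true_cluster[keep],
                true_phase = dataset$true_phase[keep])
}

#' Generate a synthetic UMI count dataset
#'
#' Draws genes x cells counts from NB(mean, size = dispersion). Each cell
#' belongs to one of K clusters (multinomial over `cluster_proportions`,
#' genotype-specific under a proportion-shift effect); each cluster's marker
#' genes have their mean multiplied by `2^marker_log2fc` in that cluster.
#' Replicated experiments receive a small per-gene log2 mean offset so
#' replicate-level tests are non-degenerate. Deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return A [count_dataset()] with ground-truth cluster (and, under a
#'   cell-cycle continuum effect, phase) labels.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  G <- config$n_genes
  K <- config$n_clusters
  genos <- config$genotype_labels
  eff <- config$effect

  n_mito <- round(G * config$mito_gene_fraction)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  mito_flags <- rep(FALSE, G)
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)
    gene_ids[mito_idx] <- sprintf("mt-gene%05d", mito_idx)
    mito_flags[mito_idx] <- TRUE
  }

  # dedicate genes to the zebrafish S/G2M sets so cycle scoring always
  # has its gene universe; they stay at baseline unless a continuum effect
  # elevates them
  s_idx <- g2m_idx <- integer(0)
  if (config$include_cycle_genes || eff$type == "cycle_continuum") {
    sets <- cc_gene_sets()
    n_cc <- length(sets$s_genes) + length(sets$g2m_genes)
    free <- which(!mito_flags)
    if (length(free) < n_cc)
      stop("n_genes too small to carry the cell-cycle gene sets")
    cc_pos <- free[seq_len(n_cc)]
    s_idx <- cc_pos[seq_along(sets$s_genes)]
    g2m_idx <- cc_pos[length(sets$s_genes) + seq_along(sets$g2m_genes)]
    gene_ids[s_idx] <- sets$s_genes
    gene_ids[g2m_idx] <- sets$g2m_genes
  }

  # disjoint marker blocks, avoiding mito and cell-cycle genes
  marker_pool <- setdiff(which(!mito_flags), c(s_idx, g2m_idx))
  n_mk <- config$n_markers_per_cluster
  if (length(marker_pool) < n_mk * K)
    stop("n_genes too small for ", n_mk, " markers in each of ", K,
         " clusters")
  marker_genes <- lapply(seq_len(K), function(k)
    marker_pool[(k - 1) * n_mk + seq_len(n_mk)])

  # per-genotype cluster proportions
  props <- lapply(genos, function(g) {
    p <- config$cluster_proportions
    if (eff$type == "proportion_shift" && g == eff$genotype) {
      p[eff$cluster] <- p[eff$cluster] * eff$factor
      p <- p / sum(p)
    }
    p
  })
  names(props) <- genos

  n_per <- config$n_cells_per_genotype
  R <- config$n_replicates_per_genotype
  genotype <- rep(genos, each = n_per)
  n_total <- length(genotype)
  replicate <- character(n_total)
  true_cluster <- integer(n_total)
  for (g in genos) {
    idx <- which(genotype == g)
    true_cluster[idx] <- sample.int(K, length(idx), replace = TRUE,
                                    prob = props[[g]])
    replicate[idx] <- paste0(g, "_exp", rep_len(seq_len(R), length(idx)))
  }

  true_phase <- rep(NA_character_, n_total)
  if (eff$type == "cycle_continuum") {
    in_cl <- which(true_cluster == eff$cluster)
    ph <- sample(c("G1", "S", "G2M"), length(in_cl), replace = TRUE,
                 prob = eff$phase_fractions[c("G1", "S", "G2M")])
    true_phase[in_cl] <- ph
  }

  # per-replicate per-gene log2 offsets
  rep_levels <- unique(replicate)
  rep_offset <- matrix(stats::rnorm(G * length(rep_levels), 0,
                                    config$replicate_log2_sd),
                       G, length(rep_levels),
                       dimnames = list(NULL, rep_levels))

  base_mu <- config$baseline_mean *
    2^stats::rnorm(G, 0, config$baseline_log2_sd)
  counts <- matrix(0L, G, n_total)
  for (i in seq_len(n_total)) {
    mu <- base_mu * 2^rep_offset[, replicate[i]]
    k <- true_cluster[i]
    mu[marker_genes[[k]]] <- mu[marker_genes[[k]]] * 2^config$marker_log2fc
    if (eff$type == "dysregulate" && k == eff$cluster &&
        genotype[i] == eff$genotype) {
      dg <- if (is.null(eff$genes)) marker_genes[[k]] else
        match(eff$genes, gene_ids)
      if (anyNA(dg)) stop("dysregulated gene not present")
      mu[dg] <- mu[dg] * 2^eff$log2fc
    }
    if (eff$type == "cycle_continuum" && !is.na(true_phase[i])) {
      if (true_phase[i] == "S") mu[s_idx] <- mu[s_idx] * eff$phase_factor
      if (true_phase[i] == "G2M") mu[g2m_idx] <- mu[g2m_idx] * eff$phase_factor
    }
    counts[, i] <- stats::rnbinom(G, size = config$dispersion, mu = mu)
  }

  dimnames(counts) <- list(gene_ids, sprintf("cell%06d", seq_len(n_total)))
  ds <- count_dataset(counts, mito_flags, genotype, replicate,
                      true_cluster = true_cluster, true_phase = true_phase)
  ds$marker_genes <- lapply(marker_genes, function(ix) gene_ids[ix])

  if (eff$type == "ablate") {
    drop <- ds$true_cluster == eff$cluster & ds$genotype == eff$genotype
    if (!any(drop))
      stop("ablate target (cluster ", eff$cluster, ", ", eff$genotype,
           ") has no cells")
    mk <- ds$marker_genes
    ds <- subset_cells(ds, !drop)
    ds$marker_genes <- mk
  }
  ds
}

#' Generate a labeled 3-D image stack
#'
#' Sharp-edged ellipsoidal expression domains of amplitude `signal_level`,
#' elongated along z so slices within the domain carry signal, on a noisy
#' flat background — the synthetic stand-in for an expression domain in a
#' wholemount HCR stain. Designated spike slices are acquisition glitches:
#' the slice content is replaced by uniform "snow" spanning the intensity
#' range, on which an entropy threshold cuts near the middle and binarizes
#' about half the slice — the sudden spike in binarized pixel counts that
#' the fallback pass must catch. The truth mask marks voxels where the
#' (post-glitch) domain profile exceeds half its amplitude.
#'
#' @param dim stack dimensions `c(z, y, x)`.
#' @param n_blobs number of domains.
#' @param signal_level domain amplitude (must exceed `background_level`).
#' @param background_level flat background intensity.
#' @param noise_sd Gaussian noise sd.
#' @param blob_sigma lateral (y, x) domain radius; the axial radius is
#'   `3 * blob_sigma` so domains span slices.
#' @param spike_slices integer z indices replaced by uniform snow.
#' @param seed integer seed.
#' @return A `labeled_stack` list with `intensities`, `true_signal_mask`,
#'   `region_masks` (left/right halves) and `spike_slices_truth`.
#' @export
generate_image_stack <- function(dim = c(8, 64, 64), n_blobs = 3,
                                 signal_level = 150, background_level = 20,
                                 noise_sd = 3, blob_sigma = 13,
                                 spike_slices = integer(0),
                                 seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (signal_level <= background_level)
    stop("signal_level must exceed background_level")
  if (n_blobs > 4) stop("at most 4 domains (one per quadrant)")
  set.seed(seed)
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  profile <- array(0, dim)
  if (n_blobs > 0) {
    # one anchor per field quadrant (jittered) keeps domains distinct
    anchors <- cbind(y = c(0.25, 0.25, 0.75, 0.75) * ny,
                     x = c(0.25, 0.75, 0.25, 0.75) * nx)
    anchors <- anchors[sample.int(4, n_blobs), , drop = FALSE]
    centers <- cbind(stats::runif(n_blobs, nz / 2 - 1, nz / 2 + 1),
                     anchors[, "y"] + stats::runif(n_blobs, -3, 3),
                     anchors[, "x"] + stats::runif(n_blobs, -3, 3))
    zc <- slice.index(profile, 1); yc <- slice.index(profile, 2)
    xc <- slice.index(profile, 3)
    sz <- 3 * blob_sigma
    for (b in seq_len(n_blobs)) {
      d2 <- (zc - centers[b, 1])^2 / sz^2 + ((yc - centers[b, 2])^2 +
        (xc - centers[b, 3])^2) / blob_sigma^2
      profile[d2 <= 1] <- signal_level
    }
  }
  for (z in spike_slices) profile[z, , ] <- 0
  true_mask <- profile >= signal_level / 2
  intens <- background_level + profile +
    array(stats::rnorm(prod(dim), 0, noise_sd), dim)
  for (z in spike_slices)
    intens[z, , ] <- stats::runif(ny * nx, 0, signal_level)
  intens <- round(pmax(intens, 0))
  half <- floor(nx / 2)
  left <- array(FALSE, dim); left[, , seq_len(half)] <- TRUE
  right <- array(FALSE, dim); right[, , (half + 1):nx] <- TRUE
  structure(list(intensities = intens,
                 true_signal_mask = true_mask,
                 region_masks = list(left = left, right = right),
                 spike_slices_truth = as.integer(spike_slices)),
            class = "labeled_stack")
}

#' Generate a synthetic eye-angle trace
#'
#' Smooth pursuit drift during moving-grating / optogenetic phases plus
#' step-like saccades at scheduled times, with Gaussian angle noise. Eye
#' angles are degrees relative to the body midline; the trial structure is
#' stationary / moving / stationary / opto / stationary.
#'
#' @param duration trace duration (s).
#' @param fs sampling rate (Hz).
#' @param saccades data.frame with columns `time`, `eye` ("left"/"right"),
#'   `direction` (+1/-1).
#' @param amplitude saccade step amplitude (deg).
#' @param pursuit_gain slow-phase velocity during moving/opto phases (deg/s).
#' @param noise_sd angle noise sd (deg).
#' @param phase_windows named list of `c(start, end)` windows for the
#'   `moving` and `opto` phases; remaining time is `stationary`.
#' @param expected_direction +1 or -1, the stimulus-consistent saccade sign.
#' @param refractory minimum spacing of scheduled saccades per eye (s).
#' @param seed integer seed.
#' @return An `eye_trace` list with `time`, `angle_left`, `angle_right`,
#'   `phase`, `expected_direction` and `truth_saccades`.
#' @export
generate_eye_trace <- function(duration = 200, fs = 50,
                               saccades = NULL, amplitude = 15,
                               pursuit_gain = 1, noise_sd = 0.2,
                               phase_windows = list(moving = c(40, 80),
                                                    opto = c(120, 180)),
                               expected_direction = 1, refractory = 0.5,
                               seed = 1L) {
  set.seed(seed)
  time <- seq(0, duration, by = 1 / fs)
  n <- length(time)
  phase <- rep("stationary", n)
  for (nm in names(phase_windows)) {
    w <- phase_windows[[nm]]
    phase[time >= w[1] & time < w[2]] <- nm
  }
  if (is.null(saccades))
    saccades <- data.frame(time = numeric(0), eye = character(0),
                           direction = numeric(0))
  stopifnot(all(saccades$time >= 0), all(saccades$time <= duration),
            all(saccades$eye %in% c("left", "right")),
            all(saccades$direction %in% c(-1, 1)))
  for (e in c("left", "right")) {
    ts <- sort(saccades$time[saccades$eye == e])
    if (length(ts) > 1 && any(diff(ts) < refractory))
      stop("overlapping saccades within the refractory window for eye ", e)
  }
  drift <- cumsum((phase %in% names(phase_windows)) * pursuit_gain / fs) *
    expected_direction
  mk_angle <- function(eye) {
    a <- drift + stats::rnorm(n, 0, noise_sd)
    ev <- saccades[saccades$eye == eye, , drop = FALSE]
    for (j in seq_len(nrow(ev)))
      a <- a + amplitude * ev$direction[j] * (time >= ev$time[j])
    a
  }
  truth <- saccades[order(saccades$time), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(time = time,
                 angle_left = mk_angle("left"),
                 angle_right = mk_angle("right"),
                 phase = phase,
                 expected_direction = expected_direction,
                 truth_saccades = truth),
            class = "eye_trace")
}
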