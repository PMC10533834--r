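#' Genotype-comparison statistics
#'
#' The bespoke statistics for asking whether cell types differ between
#' genotypes: neighborhood genotype-composition permutation z-scores on a kNN
#' graph, PC alignment against a random-split null, a cluster
#' transcriptome-alteration test, global DE filter rules, marker persistence
#' classification, cell-type proportion tests, and the worked-example
#' arithmetic (composition ratios, progenitor-enrichment chi-squared).
#'
#' @name compare_stats
NULL

#' k-nearest-neighbor graph in embedding space
#'
#' Euclidean kNN over PC scores, self excluded; distance ties are broken by
#' lower cell index.
#'
#' @param embedding an `embedding` from [pca_embed()], or a cells x dims
#'   score matrix.
#' @param k neighbors per cell (default 19, self excluded).
#' @return A `neighbor_graph` list: `index` (cells x k integer matrix), `k`.
#' @export
knn_graph <- function(embedding, k = 19) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores
  else as.matrix(embedding)
  if (nrow(scores) <= k) stop("need more cells than k")
  structure(list(index = .knn_index(scores, k), k = k),
            class = "neighbor_graph")
}

# per-cell cosine distance between neighborhood composition and a global
# expected composition, for a given label vector
.composition_distance <- function(index, labels, levels, expected) {
  n <- nrow(index)
  k <- ncol(index)
  comp <- matrix(0, n, length(levels))
  for (j in seq_along(levels)) {
    hit <- matrix(labels[index] == levels[j], n, k)
    comp[, j] <- rowSums(hit) / k
  }
  num <- comp %*% expected
  den <- sqrt(rowSums(comp^2)) * sqrt(sum(expected^2))
  1 - as.vector(num) / den
}

#' Neighborhood genotype-composition z-scores
#'
#' For each cell, the observed genotype composition of its k nearest
#' neighbors is compared with the global (expected) genotype composition by
#' cosine distance. A null distribution is generated by B full shuffles of
#' the genotype labels with the graph fixed; the per-cell z-score is
#' (observed - null mean) / null sd.
#'
#' @param graph a [knn_graph()].
#' @param genotypes genotype label per cell.
#' @param n_permutations number of label shuffles B.
#' @param seed integer seed for the shuffles.
#' @return A `composition_z` data.frame: observed_distance, null_mean,
#'   null_sd, z per cell; attributes `n_permutations`, `seed`.
#' @export
composition_zscores <- function(graph, genotypes, n_permutations = 100,
                                seed = 1L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  genotypes <- as.character(genotypes)
  levels <- sort(unique(genotypes))
  if (length(levels) < 2) stop("degenerate labels: need >= 2 genotypes")
  expected <- as.vector(table(factor(genotypes, levels))) / length(genotypes)
  obs <- .composition_distance(graph$index, genotypes, levels, expected)
  set.seed(seed)
  B <- n_permutations
  nulls <- matrix(0, B, length(genotypes))
  for (b in seq_len(B))
    nulls[b, ] <- .composition_distance(graph$index, sample(genotypes),
                                        levels, expected)
  null_mean <- colMeans(nulls)
  null_sd <- sqrt(colSums(sweep(nulls, 2, null_mean)^2) / (B - 1))
  z <- (obs - null_mean) / null_sd
  if (any(null_sd == 0)) {
    warning(sum(null_sd == 0), " cell(s) with null_sd = 0; z set to NA")
    z[null_sd == 0] <- NA_real_
  }
  out <- data.frame(observed_distance = obs, null_mean = null_mean,
                    null_sd = null_sd, z = z)
  attr(out, "n_permutations") <- B
  attr(out, "seed") <- seed
  class(out) <- c("composition_z", "data.frame")
  out
}

#' Align principal components between two datasets
#'
#' Restricts both loading matrices to the shared genes and computes all-pairs
#' cosine similarities; `best_match[i]` is the maximum absolute similarity of
#' PC i of A against any PC of B (absolute, because PC sign is arbitrary).
#'
#' @param loadings_a,loadings_b genes x PCs loading matrices with gene-id
#'   rownames.
#' @param shared_genes genes to compare on (default: rowname intersection).
#' @param n_pcs number of leading PCs to compare.
#' @return list with `similarity` (n_pcs x n_pcs) and `best_match`
#'   (length n_pcs, in [0, 1]).
#' @export
pc_alignment <- function(loadings_a, loadings_b, shared_genes = NULL,
                         n_pcs = 15) {
  if (is.null(shared_genes))
    shared_genes <- intersect(rownames(loadings_a), rownames(loadings_b))
  if (length(shared_genes) < 2) stop("no (or too few) shared genes")
  if (n_pcs > ncol(loadings_a) || n_pcs > ncol(loadings_b))
    stop("n_pcs exceeds the available loading columns")
  a <- loadings_a[shared_genes, seq_len(n_pcs), drop = FALSE]
  b <- loadings_b[shared_genes, seq_len(n_pcs), drop = FALSE]
  an <- sweep(a, 2, sqrt(colSums(a^2)), "/")
  bn <- sweep(b, 2, sqrt(colSums(b^2)), "/")
  sim <- crossprod(an, bn)
  list(similarity = sim, best_match = apply(abs(sim), 1, max))
}

#' Null PC-alignment distribution from random splits
#'
#' Randomly divides one dataset's cells into two groups at `split_ratio`,
#' runs the normalization / HVG / PCA pipeline on each half independently,
#' aligns the halves, and pools best-match values over repeats. This is the
#' null for how similar two PCs can look when the underlying biology is
#' identical and only sampling differs.
#'
#' @param dataset a [count_dataset()] (typically one genotype).
#' @param split_ratio fraction of cells in the first half.
#' @param n_repeats number of random splits (default 10).
#' @param n_pcs PCs per half.
#' @param n_hvgs HVGs per half.
#' @param seed integer seed.
#' @return numeric vector of pooled best-match values
#'   (length n_repeats * n_pcs).
#' @export
pc_null_by_split <- function(dataset, split_ratio = 0.5, n_repeats = 10,
                             n_pcs = 15, n_hvgs = 1000, seed = 1L) {
  stopifnot(inherits(dataset, "count_dataset"))
  n <- length(dataset$cell_ids)
  n1 <- round(n * split_ratio)
  if (min(n1, n - n1) < n_pcs + 1)
    stop("a split half would have fewer cells than n_pcs")
  set.seed(seed)
  pooled <- numeric(0)
  for (r in seq_len(n_repeats)) {
    first <- sample.int(n, n1)
    halves <- list(subset_cells(dataset, first),
                   subset_cells(dataset, setdiff(seq_len(n), first)))
    loads <- lapply(halves, function(h) {
      norm <- normalize_log(h)
      hv <- select_hvgs(h$counts, n = min(n_hvgs, nrow(h$counts)))
      pca_embed(norm, hv, n_pcs = n_pcs)$loadings
    })
    al <- pc_alignment(loads[[1]], loads[[2]], n_pcs = n_pcs)
    pooled <- c(pooled, al$best_match)
  }
  pooled
}

#' Compare observed PC alignment against the split null
#'
#' Two-sided rank-sum test of the observed best-match values against the
#' pooled null best-match distribution.
#'
#' @param observed_best_match numeric vector (one value per PC).
#' @param null_best_match pooled null values from [pc_null_by_split()].
#' @return list with `p_value` and the 5th percentile of the null.
#' @export
pc_alignment_test <- function(observed_best_match, null_best_match) {
  ht <- stats::wilcox.test(observed_best_match, null_best_match,
                           exact = FALSE)
  list(p_value = ht$p.value,
       null_q05 = unname(stats::quantile(null_best_match, 0.05)))
}

#' Per-cluster transcriptome alteration test
#'
#' For each cluster, the WT/mutant ratio of mean normalized expression is
#' computed for every gene detected in the cluster; the marker-gene ratio
#' distribution is compared against the all-detected-gene ratio distribution
#' with a two-sided rank-sum test, Bonferroni-corrected over clusters.
#'
#' @param norm genes x cells normalized expression.
#' @param labels cluster label per cell.
#' @param genotypes genotype label per cell.
#' @param markers a marker table from [find_markers()] (columns cluster,
#'   gene).
#' @param wt,mut the two genotype labels to compare.
#' @param detected_min_frac a gene is "detected" in a cluster when nonzero in
#'   at least this fraction of the cluster's cells.
#' @param pseudocount added to both means before the ratio.
#' @return data.frame per cluster: raw_p, bonferroni_p, n_markers,
#'   n_detected_genes, median_marker_ratio, median_all_ratio.
#' @export
alteration_test <- function(norm, labels, genotypes, markers,
                            wt = "unrelated_wt", mut = "mutant",
                            detected_min_frac = 0.05, pseudocount = 1e-9) {
  labels <- as.vector(labels)
  cl <- sort(unique(labels))
  rows <- list()
  for (k in cl) {
    inx <- labels == k
    wt_x <- inx & genotypes == wt
    mu_x <- inx & genotypes == mut
    if (!any(wt_x) || !any(mu_x))
      stop("cluster ", k, " lacks cells of both genotypes")
    det <- rowMeans(norm[, inx, drop = FALSE] > 0) >= detected_min_frac
    mk <- markers$gene[markers$cluster == k]
    mk <- intersect(mk, rownames(norm)[det])
    if (!length(mk)) {
      warning("cluster ", k, " has no detected markers; skipped")
      next
    }
    ratio <- (rowMeans(norm[det, wt_x, drop = FALSE]) + pseudocount) /
      (rowMeans(norm[det, mu_x, drop = FALSE]) + pseudocount)
    mk_ratio <- ratio[mk]
    p <- suppressWarnings(
      stats::wilcox.test(mk_ratio, ratio, exact = FALSE)$p.value)
    rows[[as.character(k)]] <- data.frame(
      cluster = k, raw_p = p, n_markers = length(mk),
      n_detected_genes = sum(det),
      median_marker_ratio = stats::median(mk_ratio),
      median_all_ratio = stats::median(ratio))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$bonferroni_p <- pmin(1, out$raw_p * nrow(out))
  out
}

#' Filter and highlight globally differentially expressed genes
#'
#' Keeps genes with adjusted p below 0.05 and highlights those whose log fold
#' change exceeds 1 in magnitude, or whose expressing-cell ratio across
#' groups is above 2 or below 0.5.
#'
#' @param de_table data.frame with columns gene, log2fc, adjusted_p, pct_a,
#'   pct_b (expressing fractions per group).
#' @param alpha adjusted-p cutoff.
#' @return the significant rows with added `pct_ratio`, `pct_ratio_infinite`
#'   and `highlighted` columns.
#' @export
global_de_filter <- function(de_table, alpha = 0.05) {
  need <- c("gene", "log2fc", "adjusted_p", "pct_a", "pct_b")
  if (!all(need %in% names(de_table)))
    stop("de_table must have columns: ", paste(need, collapse = ", "))
  sig <- de_table[de_table$adjusted_p < alpha, , drop = FALSE]
  ratio <- sig$pct_a / sig$pct_b
  inf <- sig$pct_b == 0 & sig$pct_a > 0
  ratio[inf] <- Inf
  sig$pct_ratio <- ratio
  sig$pct_ratio_infinite <- inf
  sig$highlighted <- abs(sig$log2fc) > 1 | ratio > 2 | ratio < 0.5
  rownames(sig) <- NULL
  sig
}

#' Classify a precursor marker as transient or sustained
#'
#' A marker is "sustained" if its expressing fraction reaches the threshold
#' in any cluster other than the precursor cluster, else "transient".
#'
#' @param norm genes x cells normalized expression.
#' @param labels cluster label per cell.
#' @param precursor_cluster the precursor cluster label.
#' @param marker_gene gene id.
#' @param outside_frac_threshold expressing-fraction threshold (inclusive).
#' @return "transient" or "sustained".
#' @export
marker_persistence <- function(norm, labels, precursor_cluster, marker_gene,
                               outside_frac_threshold = 0.10) {
  if (!marker_gene %in% rownames(norm))
    stop("gene ", marker_gene, " absent from the matrix")
  labels <- as.vector(labels)
  if (!precursor_cluster %in% labels) stop("precursor cluster not present")
  others <- setdiff(unique(labels), precursor_cluster)
  fr <- vapply(others, function(k)
    mean(norm[marker_gene, labels == k] > 0), numeric(1))
  if (any(fr >= outside_frac_threshold)) "sustained" else "transient"
}

#' Cell-type proportion test across experiments
#'
#' For each (genotype, experiment), the fraction of that experiment's cells
#' in each cluster; per cluster, a two-sided rank-based test between the two
#' genotypes' experiment-level fractions, Bonferroni-corrected over clusters.
#'
#' @param labels cluster label per cell.
#' @param genotypes genotype label per cell.
#' @param experiments experiment label per cell.
#' @param group_a,group_b the two genotype labels to compare.
#' @param paired use the paired signed-rank test (experiments must then match
#'   one-to-one in order); default is the unpaired rank-sum test.
#' @return list with `fractions` (cluster x unit data.frame) and `tests`
#'   (per-cluster raw_p, bonferroni_p).
#' @export
proportion_test <- function(labels, genotypes, experiments,
                            group_a = "unrelated_wt", group_b = "mutant",
                            paired = FALSE) {
  labels <- as.vector(labels)
  keep <- genotypes %in% c(group_a, group_b)
  labels <- labels[keep]; genotypes <- genotypes[keep]
  experiments <- experiments[keep]
  unit <- paste(genotypes, experiments, sep = "||")
  cl <- sort(unique(labels))
  units <- unique(unit)
  geno_of_unit <- vapply(strsplit(units, "||", fixed = TRUE), `[`, "", 1)
  if (any(table(geno_of_unit) < 2))
    stop("each genotype needs >= 2 experiments")
  tab <- table(factor(labels, cl), factor(unit, units))
  frac <- sweep(unclass(tab), 2, colSums(tab), "/")
  tests <- data.frame(cluster = cl, raw_p = NA_real_)
  for (i in seq_along(cl)) {
    fa <- frac[i, geno_of_unit == group_a]
    fb <- frac[i, geno_of_unit == group_b]
    if (stats::var(c(fa, fb)) == 0) {
      tests$raw_p[i] <- 1   # identical fractions everywhere: no evidence
    } else {
      tests$raw_p[i] <- suppressWarnings(
        stats::wilcox.test(fa, fb, paired = paired)$p.value)
    }
  }
  tests$bonferroni_p <- pmin(1, tests$raw_p * length(cl))
  fr <- as.data.frame(as.table(frac))
  names(fr) <- c("cluster", "unit", "fraction")
  fr$genotype <- vapply(strsplit(as.character(fr$unit), "||", fixed = TRUE),
                        `[`, "", 1)
  fr$experiment <- vapply(strsplit(as.character(fr$unit), "||", fixed = TRUE),
                          `[`, "", 2)
  list(fractions = fr[, c("cluster", "genotype", "experiment", "fraction")],
       tests = tests)
}

#' Ratio of two composition percentages
#'
#' E.g. percent neurons over percent progenitors-plus-early-precursors, with
#' its nearest-integer rendering as reported.
#'
#' @param percent_class_a,percent_class_b percentages (same scale).
#' @return list with `ratio` and `rounded`.
#' @export
composition_ratio <- function(percent_class_a, percent_class_b) {
  if (percent_class_b == 0) stop("denominator percentage is zero")
  r <- percent_class_a / percent_class_b
  list(ratio = r, rounded = round(r))
}

#' Chi-squared enrichment test on a 2x2 count table
#'
#' Pearson chi-squared without continuity correction (counts here are in the
#' thousands, where the correction is immaterial).
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
enrichment_chisq <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
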