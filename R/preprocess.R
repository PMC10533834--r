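#' Minimal scRNA-seq preprocessing core
#'
#' QC filtering, library-size log-normalization, vst-style highly-variable
#' gene selection, PCA and modularity-based graph clustering, with the study's
#' stated parameters as defaults (200-4000 genes/cell, 400-8000 UMIs/cell,
#' 12% mitochondrial cap; 2000 HVGs; positive-only rank-sum markers at
#' log2FC >= 0.75, min.pct 0.25, Bonferroni-adjusted p < 0.05).
#'
#' @name preprocess
NULL

#' QC thresholds
#'
#' All bounds are inclusive.
#'
#' @param min_genes,max_genes detected genes per cell.
#' @param min_umis,max_umis total UMIs per cell.
#' @param max_mito_frac maximum mitochondrial fraction of counts.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 4000,
                          min_umis = 400, max_umis = 8000,
                          max_mito_frac = 0.12) {
  stopifnot(min_genes < max_genes, min_umis < max_umis,
            max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umis = min_umis, max_umis = max_umis,
                 max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Filter cells on QC criteria
#'
#' Retains cells whose detected-gene count, UMI total and mitochondrial
#' fraction all fall inside the (inclusive) threshold ranges; the report
#' lists each criterion per cell.
#'
#' @param dataset a [count_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `dataset` (filtered) and `report` (per-cell data.frame
#'   with columns n_genes, n_umis, mito_frac, pass_genes, pass_umis,
#'   pass_mito, pass).
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (is.null(dataset$mito_flags)) stop("mito flags are required for QC")
  cnt <- dataset$counts
  n_genes <- colSums(cnt > 0)
  n_umis <- colSums(cnt)
  mito <- if (any(dataset$mito_flags))
    colSums(cnt[dataset$mito_flags, , drop = FALSE]) / pmax(n_umis, 1)
  else rep(0, ncol(cnt))
  report <- data.frame(
    cell_id = dataset$cell_ids,
    n_genes = n_genes, n_umis = n_umis, mito_frac = mito,
    pass_genes = n_genes >= thresholds$min_genes &
      n_genes <= thresholds$max_genes,
    pass_umis = n_umis >= thresholds$min_umis &
      n_umis <= thresholds$max_umis,
    pass_mito = mito <= thresholds$max_mito_frac,
    row.names = NULL)
  report$pass <- report$pass_genes & report$pass_umis & report$pass_mito
  if (!any(report$pass))
    stop("no cells survive QC (failed genes: ", sum(!report$pass_genes),
         ", umis: ", sum(!report$pass_umis),
         ", mito: ", sum(!report$pass_mito), ")")
  list(dataset = subset_cells(dataset, report$pass), report = report)
}

#' Library-size log-normalization
#'
#' Scales each cell to a fixed library size, then log(1 + x).
#'
#' @param dataset a [count_dataset()] or a genes x cells count matrix.
#' @param scale_factor target library size (default 10,000).
#' @return genes x cells matrix of log-normalized expression.
#' @export
normalize_log <- function(dataset, scale_factor = 1e4) {
  cnt <- if (inherits(dataset, "count_dataset")) dataset$counts else dataset
  tot <- colSums(cnt)
  if (any(tot == 0)) stop("cell(s) with zero total UMIs: ",
                          paste(colnames(cnt)[tot == 0], collapse = ", "))
  log1p(sweep(cnt, 2, scale_factor / tot, "*"))
}

#' Select highly variable genes (vst scheme)
#'
#' Ranks genes by the variance of clipped standardized counts: a loess fit of
#' log10(variance) on log10(mean) gives each gene an expected sd; counts are
#' standardized with the observed mean and that sd, clipped at sqrt(n_cells),
#' and the variance of the clipped values is the ranking statistic. Ties are
#' broken lexicographically by gene id.
#'
#' @param counts genes x cells raw count matrix (or [count_dataset()]).
#' @param n number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of `n` gene ids, highest standardized variance
#'   first.
#' @export
select_hvgs <- function(counts, n = 2000, loess_span = 0.3) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  if (n > nrow(counts)) stop("n exceeds the number of genes")
  nc <- ncol(counts)
  mu <- rowMeans(counts)
  v <- rowSums((counts - mu)^2) / (nc - 1)
  sv <- numeric(nrow(counts))
  ok <- v > 0 & mu > 0
  if (sum(ok) > 2) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span)
    exp_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(nc)
    z <- (counts[ok, , drop = FALSE] - mu[ok]) / exp_sd
    z <- pmin(pmax(z, -clip), clip)
    zbar <- rowMeans(z)
    sv[ok] <- rowSums((z - zbar)^2) / (nc - 1)
  }
  ord <- order(-sv, rownames(counts), method = "radix")
  rownames(counts)[ord[seq_len(n)]]
}

#' Principal component embedding
#'
#' PCA of centered, per-gene unit-variance expression over the selected
#' genes. Loadings have unit-norm columns; each PC's sign is fixed so that
#' its largest-magnitude loading entry is positive.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param genes gene ids to use (e.g. from [select_hvgs()]).
#' @param n_pcs number of components.
#' @return An `embedding` list: `loadings` (genes x n_pcs), `scores`
#'   (cells x n_pcs), `explained_variance`, `gene_ids`, `n_pcs`.
#' @export
pca_embed <- function(norm, genes = rownames(norm), n_pcs = 14) {
  x <- norm[genes, , drop = FALSE]
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds min(genes, cells)")
  xs <- t(scale(t(x)))               # center and unit-scale each gene
  xs[!is.finite(xs)] <- 0            # zero-variance genes contribute nothing
  pr <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE, rank. = n_pcs)
  load <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  flip <- apply(load, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  structure(list(loadings = load, scores = scores,
                 explained_variance = pr$sdev[seq_len(n_pcs)]^2,
                 gene_ids = rownames(load), n_pcs = n_pcs),
            class = "embedding")
}

# chunked exact kNN in embedding space; ties broken by lower cell index
.knn_index <- function(scores, k, chunk = 512L) {
  n <- nrow(scores)
  if (n <= k) stop("need more cells than k")
  sq <- rowSums(scores^2)
  idx <- matrix(0L, n, k)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * scores[s:e, , drop = FALSE] %*%
      t(scores)
    for (i in seq_len(e - s + 1)) {
      d <- d2[i, ]
      d[s + i - 1] <- Inf
      idx[s + i - 1, ] <- order(d, method = "radix")[seq_len(k)]
    }
  }
  idx
}

#' Graph-based clustering of an embedding
#'
#' Builds a kNN graph (Euclidean in PC space, k_graph neighbors, undirected
#' union of directed edges) and runs Leiden modularity community detection.
#' Deterministic given `seed`.
#'
#' @param embedding an `embedding` from [pca_embed()].
#' @param resolution modularity resolution parameter.
#' @param k_graph number of graph neighbors.
#' @param seed integer seed for the community detection.
#' @return A `cluster_labels` list: integer `label` per cell, `resolution`,
#'   `k_graph`, `seed`.
#' @export
cluster_cells <- function(embedding, resolution = 1, k_graph = 20,
                          seed = 1L) {
  scores <- embedding$scores
  if (nrow(scores) <= k_graph) stop("fewer cells than k_graph")
  idx <- .knn_index(scores, k_graph)
  n <- nrow(scores)
  edges <- cbind(rep(seq_len(n), k_graph), as.vector(idx))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  com <- igraph::cluster_leiden(g, objective_function = "modularity",
                                resolution = resolution, n_iterations = 3)
  structure(list(label = as.integer(igraph::membership(com)),
                 resolution = resolution, k_graph = k_graph, seed = seed),
            class = "cluster_labels")
}

#' Positive marker genes per cluster
#'
#' One-vs-rest two-sided rank-sum test per gene on normalized expression,
#' keeping genes with avg_log2fc at or above the threshold (positive only by
#' default), expressing fraction max(pct_in, pct_out) >= min_pct, and
#' Bonferroni-adjusted p (over all genes in the matrix) below `alpha`.
#'
#' @param norm genes x cells normalized expression.
#' @param labels cluster label per cell.
#' @param only_pos keep only positively enriched genes.
#' @param logfc_threshold minimum avg_log2fc.
#' @param min_pct minimum expressing fraction in either group.
#' @param alpha adjusted-p cutoff.
#' @return data.frame (cluster, gene, avg_log2fc, pct_in, pct_out, raw_p,
#'   adjusted_p), sorted by cluster then adjusted_p.
#' @export
find_markers <- function(norm, labels, only_pos = TRUE,
                         logfc_threshold = 0.75, min_pct = 0.25,
                         alpha = 0.05) {
  labels <- as.vector(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters")
  n_genes_total <- nrow(norm)
  out <- list()
  for (k in cl) {
    inx <- labels == k
    if (sum(inx) < 3) {
      warning("cluster ", k, " has fewer than 3 cells; skipped")
      next
    }
    xin <- norm[, inx, drop = FALSE]
    xout <- norm[, !inx, drop = FALSE]
    mean_in <- rowMeans(expm1(xin))
    mean_out <- rowMeans(expm1(xout))
    lfc <- log2(mean_in + 1) - log2(mean_out + 1)
    pct_in <- rowMeans(xin > 0)
    pct_out <- rowMeans(xout > 0)
    keep <- pmax(pct_in, pct_out) >= min_pct &
      (if (only_pos) lfc >= logfc_threshold else abs(lfc) >= logfc_threshold)
    genes <- rownames(norm)[keep]
    if (!length(genes)) next
    raw <- vapply(genes, function(gn)
      stats::wilcox.test(xin[gn, ], xout[gn, ], exact = FALSE)$p.value,
      numeric(1))
    adj <- pmin(1, raw * n_genes_total)
    sel <- adj < alpha
    if (!any(sel)) next
    df <- data.frame(cluster = k, gene = genes[sel],
                     avg_log2fc = lfc[keep][sel],
                     pct_in = pct_in[keep][sel], pct_out = pct_out[keep][sel],
                     raw_p = raw[sel], adjusted_p = adj[sel],
                     row.names = NULL)
    out[[as.character(k)]] <- df[order(df$adjusted_p, df$gene), ]
  }
  if (!length(out))
    return(data.frame(cluster = integer(0), gene = character(0),
                      avg_log2fc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), raw_p = numeric(0),
                      adjusted_p = numeric(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}
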