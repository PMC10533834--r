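#' Cell-cycle phase scoring
#'
#' Binned-control (Tirosh-style) S/G2M scoring with the zebrafish S-phase and
#' G2M-phase gene lists shipped with the package, phase assignment by the
#' larger positive score, and a genotype comparison of per-experiment phase
#' proportions.
#'
#' @name cellcycle
NULL

#' Zebrafish cell-cycle gene sets
#'
#' The 50-symbol S-phase and 52-symbol G2M-phase zebrafish gene lists,
#' shipped as plain-text files (one symbol per line).
#'
#' @return list with character vectors `s_genes` and `g2m_genes`.
#' @export
cc_gene_sets <- function() {
  rd <- function(f) readLines(system.file("extdata", f,
                                          package = "visdevstats",
                                          mustWork = TRUE))
  out <- list(s_genes = rd("s_genes_zebrafish.txt"),
              g2m_genes = rd("g2m_genes_zebrafish.txt"))
  stopifnot(!anyDuplicated(out$s_genes), !anyDuplicated(out$g2m_genes),
            !length(intersect(out$s_genes, out$g2m_genes)))
  out
}

#' Score a gene set against expression-matched controls
#'
#' Genes are binned into `n_bins` equal-frequency bins by mean expression;
#' for each set gene, `n_ctrl` control genes are drawn from its bin
#' (excluding set genes, with replacement when the bin is small). The
#' per-cell score is the mean expression of the set minus the mean expression
#' of the pooled controls. Deterministic given `seed`.
#'
#' @param norm genes x cells normalized expression.
#' @param gene_set character vector of gene ids.
#' @param n_bins number of expression bins.
#' @param n_ctrl controls sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return numeric per-cell score.
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  present <- intersect(gene_set, rownames(norm))
  if (!length(present))
    stop("no gene of the set is present; missing: ",
         paste(utils::head(setdiff(gene_set, rownames(norm)), 10),
               collapse = ", "))
  set.seed(seed)
  gm <- rowMeans(norm)
  bin <- ceiling(rank(gm, ties.method = "first") * n_bins / length(gm))
  ctrl <- character(0)
  for (g in present) {
    pool <- rownames(norm)[bin == bin[g] & !(rownames(norm) %in% gene_set)]
    if (!length(pool)) next
    ctrl <- c(ctrl, sample(pool, n_ctrl,
                           replace = length(pool) < n_ctrl))
  }
  if (!length(ctrl)) stop("no control genes available")
  colMeans(norm[present, , drop = FALSE]) -
    colMeans(norm[ctrl, , drop = FALSE])
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' G2M if the G2M score is the (strictly positive) maximum, S if the S score
#' is; a cell with neither score positive is G1. An exact positive tie goes
#' to S.
#'
#' @param s_score,g2m_score numeric vectors.
#' @return character vector in {"G1", "S", "G2M"}.
#' @export
assign_phase <- function(s_score, g2m_score) {
  if (any(!is.finite(s_score)) || any(!is.finite(g2m_score)))
    stop("non-finite cell-cycle score")
  out <- rep("G1", length(s_score))
  out[g2m_score > s_score & g2m_score > 0] <- "G2M"
  out[s_score >= g2m_score & s_score > 0] <- "S"
  out
}

#' Score S and G2M and assign phases
#'
#' @param norm genes x cells normalized expression.
#' @param gene_sets list with `s_genes` and `g2m_genes`
#'   (default [cc_gene_sets()]).
#' @inheritParams score_gene_set
#' @return data.frame with s_score, g2m_score, phase per cell.
#' @export
score_cell_cycle <- function(norm, gene_sets = cc_gene_sets(), n_bins = 25,
                             n_ctrl = 50, seed = 1L) {
  s <- score_gene_set(norm, gene_sets$s_genes, n_bins, n_ctrl, seed = seed)
  g2m <- score_gene_set(norm, gene_sets$g2m_genes, n_bins, n_ctrl,
                        seed = seed + 1L)
  data.frame(s_score = s, g2m_score = g2m, phase = assign_phase(s, g2m),
             row.names = NULL)
}

#' Compare phase proportions between genotypes
#'
#' Per-experiment phase fractions, then a two-sided rank-based test per phase
#' between the genotype groups (same machinery as [proportion_test()]).
#'
#' @param phases phase label per cell.
#' @param genotypes genotype label per cell.
#' @param experiments experiment label per cell.
#' @inheritParams proportion_test
#' @return list with `fractions` and `tests` (per-phase raw_p, bonferroni_p).
#' @export
phase_proportion_test <- function(phases, genotypes, experiments,
                                  group_a = "unrelated_wt",
                                  group_b = "mutant", paired = FALSE) {
  res <- proportion_test(phases, genotypes, experiments,
                         group_a = group_a, group_b = group_b,
                         paired = paired)
  names(res$tests)[names(res$tests) == "cluster"] <- "phase"
  names(res$fractions)[names(res$fractions) == "cluster"] <- "phase"
  res
}
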