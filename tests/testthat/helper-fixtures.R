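# small shared fixtures; heavier simulation-based checks live in
# test-acceptance.R at the sizes documented in the methods vignette

small_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 400, n_cells_per_genotype = 150, n_clusters = 3,
               cluster_proportions = c(0.4, 0.3, 0.3),
               n_markers_per_cluster = 10, marker_log2fc = 3,
               n_replicates_per_genotype = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

separable_config <- function(seed = 1L, ...) {
  small_config(seed = seed, n_genes = 1000, n_cells_per_genotype = 300,
               n_markers_per_cluster = 30, marker_log2fc = 5, ...)
}

# brute-force two-class entropy objective used as the threshold oracle
oracle_entropy_threshold <- function(histogram, alpha) {
  p <- histogram / sum(histogram)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:255) {
    p0 <- p[seq_len(t + 1)]; p1 <- p[(t + 2):256]
    P0 <- sum(p0); P1 <- sum(p1)
    if (t == 255 || P0 <= 0 || P1 <= 0) next
    if (alpha == 1) {
      q0 <- p0[p0 > 0] / P0; q1 <- p1[p1 > 0] / P1
      h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    } else {
      h <- (log(sum((p0 / P0)^alpha)) + log(sum((p1 / P1)^alpha))) /
        (1 - alpha)
    }
    if (h > best + 1e-12) {
      best <- h; best_t <- t
    }
  }
  best_t
}

random_histogram <- function(seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {           # two Gaussian-shaped modes
    x <- c(rnorm(3000, 60, 12), rnorm(1000, 190, 20))
  } else if (kind == 1) {    # skewed background plus sparse bright tail
    x <- c(rgamma(4000, 2, 0.1), runif(200, 120, 255))
  } else {                   # heavy uniform component
    x <- c(runif(2000, 0, 255), rnorm(2000, 100, 30))
  }
  tabulate(pmin(pmax(round(x), 0), 255) + 1, 256)
}
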