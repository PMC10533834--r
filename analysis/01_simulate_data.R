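#!/usr/bin/env Rscript
# Simulate the study-shaped inputs every later stage consumes: a
# three-genotype scRNA-seq count matrix written as a 10x-style triplet,
# HCR-like image stacks with anatomical masks, and OKR eye traces.

library(visdevstats)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260927L

cfg <- synth_config(n_genes = 1500, n_cells_per_genotype = 1200,
                    n_clusters = 8, n_markers_per_cluster = 20,
                    marker_log2fc = 2.5, n_replicates_per_genotype = 4,
                    seed = seed)
ds <- generate_counts(cfg)
write_counts_10x(ds, file.path(out, "counts"))
message("counts: ", nrow(ds$counts), " genes x ", ncol(ds$counts),
        " cells across ", length(unique(ds$replicate)), " experiments")

for (g in c("geneA", "geneB")) {
  for (r in 1:2) {
    st <- generate_image_stack(blob_sigma = 6,
                               spike_slices = if (r == 1) 4L else integer(0),
                               seed = seed + match(g, c("geneA", "geneB")) *
                                 10L + r)
    write_stack_tiff(st$intensities,
                     file.path(out, sprintf("hcr_%s_rep%d.tiff", g, r)))
  }
}
message("HCR stacks written for geneA/geneB, 2 replicates each")

sac <- data.frame(
  time = c(125, 132, 139, 146, 153, 160, 127, 134, 141, 148, 155),
  eye = c(rep("left", 6), rep("right", 5)),
  direction = c(1, 1, 1, 1, -1, 1, 1, 1, 1, -1, 1))
tr <- generate_eye_trace(saccades = sac, seed = seed)
write_eye_trace(tr, file.path(out, "okr_trace.csv"))
message("eye trace written (", length(tr$time), " samples)")
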