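# visdevstats

Does a brain region still develop its full complement of cell types when a
major input is missing? In the larval zebrafish, *lakritz* (*atoh7*) mutants
never form retinal ganglion cells, so their retinorecipient brain areas
(pretectum, thalamus, tectum) develop without any retinal input. Answering
"is any cell type missing or altered?" from clustered single-cell RNA-seq
requires statistics that standard toolkits do not ship. This package
implements that comparison battery, the accompanying HCR-FISH image
quantification, and the optokinetic-response (OKR) behavioral index, together
with synthetic-data generators that emulate the three-genotype study design
(unrelated wildtype, sibling wildtype, mutant) so the whole pipeline is
testable end to end without any downloads.

## What is implemented

**Genotype-comparison statistics** (`compare_stats`):

- *Neighborhood composition z-scores.* For each cell, the genotype
  composition of its k = 19 nearest neighbors (Euclidean, PC space) is
  compared with the global genotype composition by cosine distance,
  d_i = 1 − cos(c_i, p). B label shuffles give per-cell null moments and
  z_i = (d_i − μ_null) / σ_null. Local "hotspots" of one genotype show up as
  extreme z.
- *PC alignment with a random-split null.* Loading matrices of two
  independently processed datasets are compared by all-pairs cosine
  similarity on shared genes; each PC's best match (max |cos|) is tested
  (two-sided rank-sum) against the best matches of random splits of one
  dataset re-processed from scratch.
- *Cluster transcriptome-alteration test.* Per cluster, the WT/mutant ratio
  of mean expression over detected genes; the marker-gene ratio distribution
  is compared with the all-gene ratio distribution (rank-sum, Bonferroni
  over clusters).
- *Cell-type proportion tests* across replicated experiments, exact
  rank-based two-sided p, Bonferroni over clusters; the same machinery
  compares G1/S/G2M phase fractions.
- *Worked-example arithmetic*: composition ratios and the 2×2
  neurons-vs-progenitors chi-squared (uncorrected Pearson).

**In-silico cluster ablation** (`ablation`): remove one genotype's cells
from one cluster, re-process blind (normalize → HVG → PCA → cluster, no
batch correction), transfer reference identities by nearest centroid in the
new PC space, and test each reference cluster for mutant depletion
(hypergeometric lower tail). A cluster counts as "missing" when it ranks
first, passes Bonferroni, and holds fewer than half its expected mutants.
`power_curve()` wraps this into a detection-power analysis over cluster
sizes.

**Preprocessing core** (`preprocess`): QC (200–4000 genes/cell, 400–8000
UMIs/cell, ≤12% mitochondrial counts, inclusive bounds), library-size
log-normalization to 10,000, vst-style HVG ranking, PCA with a fixed sign
convention, Leiden modularity clustering on a kNN graph, and positive
rank-sum markers (log2FC ≥ 0.75, min.pct 0.25, Bonferroni-adjusted p <
0.05).

**Cell-cycle scoring** (`cellcycle`): Tirosh-style binned-control scoring
with the 50-gene zebrafish S list and 52-gene G2M list shipped under
`inst/extdata/`; phase = the larger positive score, else G1.

**HCR-FISH quantification** (`hcr_quant`): per-slice Rényi-entropy
binarization (Sahoo et al. 1997 combination over α ∈ {0.5, 1, 2}) with a
Kapur maximum-entropy fallback on slices whose binarized pixel count spikes
above 3× the neighboring-slice median; intensity-weighted masks; per-region
signal sums and background means; per-gene and per-region normalizations.

**OKR index** (`okr`): velocity-threshold saccade detection with a
refractory period; index = saccades in the expected direction minus the
opposite direction within the stimulation window, averaged over both eyes.

**Synthetic data** (`syndata`): negative-binomial UMI counts (log-normal
gene means, cluster marker elevation, replicate offsets) with injectable
effects — cluster ablation, gene-set dysregulation, proportion shifts, a
cell-cycle continuum; sharp-edged 3-D image domains with spike-slice
glitches; pursuit-plus-saccade eye traces. All generators are deterministic
given a seed.

## Worked example

```r
library(visdevstats)

cfg <- synth_config(n_genes = 1000, n_cells_per_genotype = 667,
                    n_clusters = 8, marker_log2fc = 2, seed = 1)
ds   <- generate_counts(cfg)                      # 2001 cells, 3 genotypes
norm <- normalize_log(ds)
emb  <- pca_embed(norm, select_hvgs(ds$counts, 500), n_pcs = 14)
cz   <- composition_zscores(knn_graph(emb, k = 19), ds$genotype,
                            n_permutations = 100, seed = 1)
mean(abs(cz$z) > 1.96, na.rm = TRUE)
#> [1] 0.06396802

composition_ratio(82.6, 4.4)$rounded   # wildtype neurons : progenitors
#> [1] 19
composition_ratio(73.5, 7.9)$rounded   # mutant
#> [1] 9
```

No genotype effect was injected, so ~5% of cells exceed |z| = 1.96 — the
neighborhood test is calibrated. The two ratios are the package's
worked-example arithmetic on the reported class percentages: progenitors
and early precursors are enriched roughly twofold relative to neurons when
retinal input is absent.

The `analysis/` directory holds the numbered drivers
(`01_simulate_data.R` … `05_okr_index.R`) that run the full workflow and
write tables under `results/`.

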