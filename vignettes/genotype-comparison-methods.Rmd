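---
title: "Comparing cell-type development between genotypes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cell-type development between genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
models behind each stage, the parameters that matter and their defaults, what
the synthetic-data generators do and do not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to be
made. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The scientific setting

The package targets a three-condition design: unrelated wildtype, sibling
wildtype, and a blind mutant (*lakritz*/*atoh7*, lacking all retinal ganglion
cells), each profiled by droplet scRNA-seq in several replicated experiments.
The question is negative in form — *no* cell type should be missing or
transcriptionally altered if visual-brain development is retina-independent —
which is why the battery combines several complementary statistics rather
than a single test, and why an explicit power analysis (the in-silico
ablation) is part of the package: a null result is only meaningful if a real
missing cluster would have been caught.

## Preprocessing core

QC retains cells with 200–4000 detected genes, 400–8000 UMIs and at most 12%
mitochondrial counts. All bounds are inclusive: the source ranges are stated
without boundary semantics, and inclusiveness is the convention that keeps a
cell at exactly 12% mitochondrial fraction. Normalization is library-size
scaling to 10,000 followed by log(1 + x); 10,000 is the dominant toolkit
default, used because only non-default parameters were specified upstream.

Highly variable genes are ranked by the vst scheme: a loess fit (span 0.3)
of log10 variance on log10 mean gives each gene an expected sd; counts are
standardized with the observed mean and that sd, clipped at sqrt(n_cells),
and genes are ranked by the variance of the clipped values. Exact ties break
lexicographically by gene id so the selection is reproducible.

PCA operates on centered, per-gene unit-variance expression of the selected
genes. PC signs are arbitrary in principle; each component is oriented so
its largest-magnitude loading is positive, making repeated runs bit
identical. Clustering builds an exact Euclidean kNN graph (k_graph = 20,
ties broken toward lower cell index) and runs Leiden modularity community
detection; the community-detection seed is an explicit argument and is
logged in run manifests. Upstream analyses used dataset-specific PC counts
(14/18/20/22) and resolutions (1/1.6/1.8/2/2.5); no single value is
canonical, so both are plain arguments with defaults n_pcs = 14,
resolution = 1.

Markers are positive-only one-vs-rest two-sided rank-sum tests on
log-normalized data, filtered at avg_log2fc ≥ 0.75 and expressing fraction
≥ 0.25 in either group, with Bonferroni correction over all genes in the
matrix — the reference toolkit's convention, kept so adjusted p values are
comparable.

## The comparison statistics

**Neighborhood composition z-scores.** Composition vectors are raw genotype
fractions among the k = 19 nearest neighbors (self excluded); the expected
vector is the global genotype fraction; the distance is 1 − cosine
similarity, uncentered, because no centering was specified upstream. The
null shuffles genotype labels over all cells with the graph fixed
(B = 100 by default; B is not specified upstream and is exposed). Cells
whose null sd is zero get a missing z with a warning rather than an
infinite score. The neighborhood space is PC scores with Euclidean
distance: the upstream description computes neighborhoods adjacent to a 2-D
embedding without naming the space, and PC space is the reproducible
choice — a documented deviation.

**PC alignment.** Cosine similarities are compared in absolute value
because a PC's sign carries no information. The null re-runs the entire
normalization/HVG/PCA pipeline on each random half, rather than resampling
loadings, so the null carries the full pipeline variability. The observed
and null comparisons must use matched split sizes: stability of a PC
depends strongly on n, and an unmatched comparison measures sample size,
not biology.

**Alteration and proportion tests.** The upstream text names the Wilcoxon
signed-rank test for comparisons that are structurally two-sample with
unequal sizes (marker ratios vs all-gene ratios; proportions across
unpaired experiment groups). The package uses the two-sided rank-sum
(Mann–Whitney) test with exact small-sample p values as the default and
offers `paired = TRUE` where a pairing exists. Expression ratios use a
1e-9 pseudocount on means; "detected in a cluster" means nonzero in at
least 5% of the cluster's cells. When every experiment shows identical
fractions the test statistic is degenerate and p is defined as 1. The
enrichment chi-squared is the uncorrected Pearson statistic: with counts in
the thousands the continuity correction is immaterial.

## Cell-cycle scoring

Scoring is the binned-control scheme: genes are binned into 25
equal-frequency bins by mean expression; each set gene draws 50 controls
from its bin (set genes excluded; with replacement when a bin is small);
the score is mean set expression minus mean control expression per cell.
Phase is G2M or S if the respective score is the strictly positive maximum,
else G1; an exact positive tie goes to S (ties are measure-zero in real
data; the rule exists for reproducibility). The 50-gene S and 52-gene G2M
zebrafish lists ship as plain text under `inst/extdata/`. n_bins and
n_ctrl were not specified upstream; the defaults are the reference
implementation's.

## In-silico ablation

One genotype's cells are removed from one cluster; the truncated matrix is
re-processed from scratch with no batch correction (correction can absorb
exactly the signal being tested). Detection had to be automated where the
original was visual inspection of an embedding: reference cluster
identities are transferred to surviving cells by nearest reference-centroid
in the re-computed PC space, and each reference cluster is tested for
mutant depletion with a hypergeometric lower tail under the global mutant
fraction.

The verdict requires three conditions: the ablated cluster ranks first by
depletion p, passes Bonferroni over testable clusters at alpha = 0.05, and
holds fewer than half its expected mutant cells. The third condition is
this package's addition. A detector with only the first two is exactly
calibrated — its false-positive rate on null data equals the nominal alpha
— which makes an empirical "at most 5% false positives over 20 null
replicates" expectation a coin flip. "Missing" in the visual-inspection
sense means a population that is grossly absent, not marginally depleted;
the 0.5 expectation gate encodes that semantics and drives the measured
null false-positive rate to zero at the study conditions while leaving
power at the 5%-cluster-fraction fixture intact (both measured in
`test-acceptance.R` and the acceptance script). The centroid-transfer rule
is likewise this package's definition — the original re-used known
identities and inspected a 2-D embedding by eye, which no deterministic
test can reproduce.

## HCR-FISH quantification

Histograms use 256 bins after per-slice min-max rescaling — the reference
algorithms are 8-bit and the original bit depth is unstated. Kapur
thresholds maximize the summed Shannon entropies of the two classes; Rényi
thresholds maximize the order-α Rényi entropy sum for α ∈ {0.5, 1, 2} and
combine the three sorted candidates with the Sahoo et al. (1997)
proximity-weighting rule, as in the standard auto-threshold reference
implementation. Each per-α threshold is independently oracle-tested against
exhaustive search so any discrepancy in the combination rule would be
isolated. Ties take the lowest threshold; classes must be nonempty.

A slice is a spike when its binarized pixel count exceeds 3× the median of
its ±2 neighbors ("sudden spikes compared to surrounding slices" is the
whole upstream specification; the factor and window are exposed
parameters). Spiked slices are re-thresholded with the Kapur objective and
the method per slice is recorded. Pixels strictly above threshold are
signal; the quantified stack is mask × intensity. Region quantification
averages replicates, then normalizes per gene (row maximum = 1) and — on
background-normalized values (signal sum / mean intensity of in-region
non-signal pixels) — per region (column maximum = 1). Image registration is
out of scope; masks are assumed co-registered.

## OKR index

No saccade criterion was stated upstream, so detection is a velocity
threshold (default 100 deg/s at 50 Hz sampling) with a 0.5 s refractory
period per eye, both exposed and logged. The index is the raw count
difference (expected minus opposite direction) within the stimulation
window, averaged over both eyes; it is not normalized per unit time, which
matches its described behavior of hovering near zero under spontaneous
movement.

## Synthetic data: what it emulates, and what it does not

Counts are negative binomial per gene (the standard UMI noise model; none
was stated upstream) with log-normal per-gene means (sd 1 log2 unit around
the configured median). The log-normal spread matters twice: HVG selection
is meaningless on a flat baseline, and binned-control cell-cycle scoring
degenerates when all baseline genes share one mean — the controls then
collapse onto the other cycle set. Clusters are multinomial with
configurable proportions; each cluster elevates its disjoint marker block
by 2^marker_log2fc; replicated experiments get per-gene log2 offsets (sd
0.05) so experiment-level tests are non-degenerate; 2% of genes carry the
zebrafish "mt-" prefix and the mito flag. The 102 cell-cycle gene symbols
are always present (disable with `include_cycle_genes = FALSE`); a
cycle-continuum effect assigns phases within one cluster and multiplies the
phase's gene set by 4.

Injectable effects mirror the alternative hypotheses: `ablate` (a cluster
empty in one genotype), `dysregulate` (a gene set scaled in one cluster and
genotype), `proportion_shift` (a cluster's sampling proportion scaled in
one genotype), `cycle_continuum`. One property discovered while validating:
dysregulating a cluster's *own markers* barely rotates principal components
— per-gene standardization preserves the cluster-contrast direction — so
the PC-alignment sensitivity check injects a module of previously
uninformative genes instead, which genuinely adds an expression direction.

Not emulated: gene–gene correlation beyond cluster structure, doublets,
ambient RNA, batch effects beyond the replicate offsets, library-size
gradients within a genotype. Passing tests therefore show the statistics
behave correctly under the stated noise model, not that real data meet that
model.

Image stacks are sharp-edged ellipsoidal domains (lateral radius
`blob_sigma`, axial 3×) on jittered field quadrants over a flat noisy
background. Sharp edges are deliberate: with graded Gaussian rims, a large
voxel shell lies between any threshold surface and a half-maximum truth
mask, and voxel-level agreement then measures rim geometry rather than
threshold quality. Spike slices are uniform-snow acquisition glitches; a
constant additive offset — the first candidate artifact — is removed
exactly by per-slice min-max rescaling and cannot perturb an entropy
threshold, whereas snow forces a near-balanced split and a reliable count
spike. Eye traces are linear pursuit drift during moving/optogenetic phases
plus step saccades and Gaussian angle noise.

## Problem sizes and fixtures

Simulation-based checks run at sizes chosen for a single CPU while keeping
every estimate stable: neighborhood calibration at 2001 cells × 1000 genes
over 5 seeds (B = 100); ablation power at 2100 cells, K = 8, 30 markers per
cluster at log2FC 2 — many markers of modest effect, the hardest regime the
detector is expected to handle — with 20 ablated plus 20 null replicates;
PC-alignment self-consistency
on a diffuse K = 8 dataset (15 PCs, 10 null splits), and injected-effect
detection on a crisp K = 4 dataset (unequal proportions, 30 markers at
log2FC 5, comparing the top 2 PCs — the stable, well-separated eigenvalue
regime; with more PCs the weakest contrast's own split instability
contaminates the null's 5th percentile). The "separable" clustering fixture
uses 30 markers per cluster at log2FC 5, where exact recovery (ARI = 1) is
robust across seeds; at weaker effect sizes a handful of boundary cells
keeps ARI just below 1 regardless of the clustering algorithm.

## Known limitations

- Batch correction (Harmony / anchor integration) is out of scope; the
  workflow accepts pre-corrected embeddings but never corrects. On real
  data with strong batch structure the joint embedding used by the
  neighborhood test would confound batch with genotype.
- The ablation detector's centroid transfer assumes roughly convex,
  separated clusters; diffuse populations that embed poorly in any space
  will be hard to detect, which mirrors the original report that dispersed
  clusters resisted visual detection.
- Entropy thresholds hug the background's upper tail by construction; on
  stacks where signal occupies a tiny voxel fraction, absolute false-positive
  counts can rival the signal. The quantification sums are
  intensity-weighted, which damps but does not remove this.
- The rank-sum tests across experiments have few units (typically 3–4 per
  genotype); their exact p values are coarse and Bonferroni across many
  clusters is conservative.
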