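---
title: "Methods: dissecting the tumor invasive niche from spatial and single-cell transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting the tumor invasive niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `spatialniche`, in the order the pipeline runs them. The
package targets the analysis pattern of infiltrative basal cell carcinoma
(BCC) studies that pair GeoMx digital spatial profiling (DSP) of
tumor–stroma interface regions with scRNA-seq of dissociated tumors, but
every stage is an ordinary function usable on its own.

## The synthetic study conditions

Statistical claims about a pipeline are only checkable against data with
known truth, so the generator (`sim_config()`, `simulate_sc_counts()`,
`simulate_dsp_probes()`) is a first-class module. Its defaults define the
study conditions all recovery tests run under:

* **Cell types and counts.** 800 tumor cells, 200 basal and 200
  differentiated keratinocytes, 250 fibroblasts and 250 T cells across 3
  patient samples, plus 50 planted low-quality cells (shrunken libraries or
  inflated mitochondrial reads) for the QC stage to remove. The tumor
  compartment dominates, as in BCC, and is large enough for subclustering
  to resolve the planted continuum.
* **Counts.** Negative binomial with variance `mu + phi mu^2`, `phi = 0.5`,
  per-cell log-normal library factors (sdlog 0.3), baseline gene means
  log-normal around 1.0. The baseline is set so that healthy cells sit well
  inside the fixed 500–6000 detected-gene QC window of a 2000-gene
  universe; the planted low-quality cells, not the QC floor, are what the
  filter removes.
* **The invasion continuum.** Each tumor cell carries a latent coordinate
  `g ~ Beta(2, 2)`; a 60-gene INF program scales as `2^(2.5 g)` and a
  60-gene NOD program as `2^(2.5 (1 - g))`. The continuum is deliberately
  the dominant biological axis — real invasive reprogramming spans
  thousands of genes, and a weaker planting would leave the embedding's
  leading variance to the depth/detection axis that log-normalization
  cannot fully remove. Fibroblasts carry an analogous activation coordinate
  driving an ECM program against a quiescent program.
* **Drivers.** An INHBA-like ligand follows `0.5 * 2^(4 g)` in tumor cells
  (sharply induced toward the infiltrative end, near-absent elsewhere,
  matching the tip-restricted expression the assay class reports) and a
  TGFB1-like control is expressed flat — the screen must find the first and
  not the second.
* **Copy number.** Segments are defined per chromosome (genes are laid out
  round-robin over 22 synthetic chromosomes) and are *patient-specific*:
  each segment multiplies the means of its genes in the tumor cells of one
  sample. A lineage segment instead multiplies all epithelial cells of
  every sample — the confounder the shared-change exclusion must mask.
  Planting identical CNVs in all samples would make the exclusion rule
  erase true CNVs, contradicting the premise that only lineage effects are
  shared across patients.
* **DSP AOIs.** 12 AOIs per (compartment × morphology) group. Each AOI's
  gene expectation is `(1 - c) * own + c * adjacent` compartment profile
  with `c ~ Beta(2, 18)` (mean 0.1 — mild contamination; no quantitative
  level is published, so this is a declared modeling choice), morphology
  log2 fold-changes of ±1.0 planted on the compartment programs, 5 probes
  per gene with log-normal efficiencies (CV 0.15), 0.5% of probes aberrant
  at 10× efficiency, 20 negative probes, and Poisson counting noise.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects between samples, spatial autocorrelation within an AOI, probe
sequence biases, or any relationship between the synthetic gene symbols
and real gene function. Passing recovery tests therefore demonstrate that
the pipeline's logic is correct under its own assumptions, not that it is
robust to those artifacts.

## Single-cell core

QC retains cells with detected genes in the inclusive window [500, 6000]
and mitochondrial and dissociation read fractions strictly below 20% — the
inclusive-bounds reading of "between" is the common convention.
Normalization is `ln(1 + count * 10^4 / total)`. Variable genes are ranked
by the residual of log variance against a degree-2 polynomial in log mean:
a deterministic, dependency-light stand-in for the loess trend of the vst
method with the same ranking intent; ties break lexicographically.

Clustering scales and centers the selected genes (clipping standardized
values at ±10), takes 25 principal components, builds a k = 20 Euclidean
kNN graph, reweights edges by the Jaccard index of (self-inclusive)
neighbor sets pruning below 1/15, and optimizes modularity with Leiden
under a fixed seed. Two scale notes: (i) with a 2000-gene universe the
canonical "top 2000 variable genes" is no selection at all, so the
pipeline default is the top 500 (top 25%), playing the role the top-10%
selection plays at whole-transcriptome scale; (ii) the resolution
parameter of igraph's Leiden on our SNN weights is not numerically
comparable to other implementations' scales — the presets 0.8 (global) and
1.0 (tumor) produce 5 global clusters and 3–5 tumor subclusters at these
cell numbers, not the larger subcluster counts seen in ~10× larger real
datasets. The modularity-limit property (resolution → 0 gives one cluster)
holds on connected SNN graphs; fully separated populations yield
disconnected graphs whose components cannot merge.

Module scores follow the bin-matched control-gene scheme: all genes are
placed into 24 equal-frequency bins by mean expression; each signature
gene draws 100 control genes with replacement from its bin under a fixed
seed; the score is mean signature expression minus mean control
expression. Bin count and control count are conventional defaults — the
method description in the literature names none.

Wilcoxon DEG uses the normal approximation with tie correction and no
continuity correction; fold-changes are `log2` ratios of `expm1`-back-
transformed means with a 1e-9 pseudocount, and BH is the default multiple-
testing correction — fold-change estimator and correction are configurable
because published tables rarely state either.

## DSP processing

Grubbs' test runs per (target, AOI) on `log2(count + 1)` with the
two-sided critical value `((n-1)/sqrt(n)) sqrt(t^2/(n-2+t^2))`,
`t = qt(alpha/(2n), n-2)`; only the most deviant probe can be flagged per
test (the single-outlier statistic tests exactly one), zero-variance probe
sets are skipped, and a probe flagged in ≥ 20% of AOIs is excluded
globally — the fraction is a platform convention, exposed as a parameter.
Collapse is the geometric mean of unflagged probe counts with zeros lifted
to 0.5 (zero-free probe sets collapse exactly; a blanket pseudocount would
distort them). Negative-probe factors are per-pool geometric means used as
background QC, not as the primary normalization. Q3 normalization scales
each AOI by `q_i / geomean(q)` with the type-7 (linear interpolation) 75th
percentile; afterwards every AOI's 75th percentile equals `geomean(q)`
exactly, and factors deviating from the median log2 factor by more than
3 MAD are QC-flagged. Morphology DEG is a Welch t-test on
`log2(normalized + 1)` — the vendor software does not name its test — with
the strict significance rule `|log2FC| > 0.4` and `p < 0.05`; raw p is
used for the call (whether published volcano plots use adjusted p is not
stated) and BH-adjusted p is reported alongside.

## Contamination filtering

Raw signatures are the significant genes split by fold-change sign;
cross-compartment overlaps are reported as a contamination diagnostic. The
filter keeps a tumor-signature gene only if (i) it is detected in ≥ 10% of
epithelial cells, (ii) its stromal/epithelial mean-expression ratio is
≤ 3, and (iii) it is not detected in ≥ 25% of the cells of *every* type
(ubiquity); mirrored for stroma. The three thresholds quantify the
qualitative removal rules ("not expressed", "low here and high there",
"ubiquitous"); they are declared choices, configurable, and every decision
is logged with the rule that fired. The epithelial compartment is defined
by annotated cell types (tumor plus keratinocytes) rather than
thresholding an epithelial marker per cell, matching the cluster-level use
of marker-positive populations.

## Inferred copy number

Steps in order: drop genes with mean raw reference count < 0.1;
log-normalize; subtract the reference mean per gene; smooth per chromosome
with a centered, end-truncated moving average (one window per gene);
subtract each cell's median across windows; clamp at ±1. The window
default is 101 genes (the inferCNV convention); the pipeline uses 51 on
the default layout because 2000 genes over 22 chromosomes leave ~91 genes
per chromosome, and segment-scale recovery runs use a denser 4-chromosome
configuration with window 101. When profiles are computed per sample for
the shared-change exclusion, the gene filter uses the *pooled* reference
mean so all samples share one window map. A window is masked when the
epithelial mean exceeds +0.15 in all samples or falls below −0.15 in all
samples; the threshold operationalizes "commonly observed in all samples"
and is exposed in the configuration. Burden is the mean squared unmasked
window value — a deliberately simple statistic to make the
tumor-vs-fibroblast comparison testable; heatmaps, not statistics, are
what the source assays publish. Two numerical caveats are tested rather
than assumed: a uniform doubling of a cell's counts cancels entirely in
normalization (the profile stays flat), and the per-cell median centering
biases the baseline when a segment (plus its smoothing shoulder) covers a
large genome fraction — segments in recovery tests are kept under ~20% of
windows for that reason.

## Niche mapping and trajectory

Cluster ranking sorts tumor subclusters by mean `T^INF − T^NOD` module
score (ties by cluster id) and relabels them TC1…TCk. Grouping follows the
realized partitions reported for this design: explicit counts when given,
otherwise quartile singletons (Low/MedLow/MedHigh/High) at k = 4 and cuts
at the rounded 25%/75% cluster quantiles into Low/Med/High otherwise
(giving 4/7/4 at k = 15). Whether the published grouping followed a rule
or inspection is unknown; the quantile rule reproduces it.

The trajectory is a deliberate simplification of principal-graph learning:
a minimum spanning tree over cluster centroids, cells projected onto their
nearest tree edge, pseudotime the geodesic distance from the root centroid
to the projection (clipped at the root, so the minimum is 0). It runs in
the leading 5 PCs — the trajectory manifold — because MSTs over centroids
in the full 25-dimensional space wander through noise dimensions; this
mirrors principal graphs being fit in low-dimensional embeddings. Its
contract is the recovery property (pseudotime correlates with the planted
gradient), not topological equivalence with any particular graph-learning
algorithm. The known failure mode, visible at some seeds, is an adjacent
swap: when the clustering splits the mid-gradient into parallel rather
than serial clusters, the tree hangs one off the other and the cell-level
correlation drops while the cluster-level ranking (which does not use the
tree) stays correct.

Moran's I is computed vectorized over genes on a symmetrized binary k = 20
kNN graph in PC space, `I = (n/W) sum w_ij z_i z_j / sum z_i^2`, with
p-values from the normal approximation under randomization assumptions and
BH q-values; constant genes are undefined (error for a single gene, NA in
the table). The trajectory gene screen keeps `I > 0.1` strictly, ordered
by decreasing I, and intersects with a shipped list of secreted CAF
activators (TGF-β superfamily, PDGFs, EGF family, FGFs, hedgehog ligands)
preserving that order. The "autocorrelation index" is treated as Moran's I
itself — no other definition is published for this screen.

## Orchestration and reproducibility

`run_all()` executes data → single-cell core → CNV → DSP → filter → niche
→ trajectory, writes every artifact as TSV/text plus a JSON manifest, and
derives per-stage seeds as `seed + 1000 * stage_index` so stages are
reproducible independently. A rerun with the same configuration is
byte-identical; the determinism test compares artifacts byte for byte.
Problem sizes throughout (1700 cells, 2000 genes, 48 AOIs, 20-replicate
recovery loops) are chosen so the full suite and the acceptance script run
comfortably on a single CPU; they are desk-scale stand-ins for the
10–20× larger real datasets.

## Limitations

* Contamination filtering assumes the scRNA-seq cell types cover the AOI
  cell composition; cell types absent from dissociated data (e.g.
  neutrophils) could leave contamination undetected.
* The shared-change exclusion masks any window that behaves consistently
  across all samples — a true CNV recurrent in every patient at the same
  position would be masked too; at realistic patient counts this is rare.
* The centroid-MST pseudotime has no branch model and assumes a single
  dominant continuum; branching topologies need a principal-graph method.
* Module-score bins depend on the dataset's mean-expression profile, so
  scores are comparable within, not across, datasets.
* The Leiden resolution scale is implementation-specific; resolution
  presets reproduce the analysis *structure* (global clustering, finer
  tumor subclustering), not a specific cluster count.
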