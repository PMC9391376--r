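# spatialniche

Integrated spatial and single-cell transcriptomics of the tumor invasive
niche.

Infiltrative basal cell carcinoma (BCC) invades as collectively migrating
epithelial strands embedded in an activated stroma. Dissecting that invasive
niche requires two complementary assays: GeoMx digital spatial profiling
(DSP), which sequences pan-cytokeratin-positive (tumor) and -negative
(stroma) areas of interest (AOIs) at tumor–stroma interfaces of nodular and
infiltrative tumors, and scRNA-seq, which resolves the cell types and the
within-tumor continuum those regions are made of. `spatialniche` implements
the full analysis chain that connects them, for computational biologists who
want each step as a tested, reusable function rather than a vendor pipeline:

- **DSP probe processing** — per-target Grubbs outlier tests on
  `log2(count + 1)` at α = 0.01, gene collapse by geometric mean of probes,
  pool-specific negative-probe background factors, a 10,000-read AOI
  minimum, and upper-quartile (Q3) normalization: each AOI is scaled by
  `q_i / geomean(q)` where `q_i` is its 75th-percentile gene count.
- **Morphology differential expression** — Welch t-tests per compartment,
  infiltrative vs nodular, significant at `|log2FC| > 0.4` and `p < 0.05`,
  yielding the four raw spatial signatures T^NOD, T^INF, S^NOD, S^INF.
- **Cross-contamination filtering** — adjacent AOIs contaminate each other,
  so stromal genes (the FN1/COL1A1 phenomenon) appear in tumor signatures.
  Each signature gene is kept only if scRNA-seq shows it detected in ≥ 10%
  of its own compartment's cells, not dominated (> 3×) by the other
  compartment's mean expression, and not ubiquitous across cell types.
- **Single-cell core** — QC (500–6000 detected genes, < 20% mitochondrial
  and dissociation reads), `ln(1 + CP10K)` normalization, variance-trend
  gene selection, SNN-graph modularity clustering, marker annotation,
  Wilcoxon DEG, LISI mixing scores, and module scoring: mean expression of
  a signature minus the mean of bin-matched random control genes.
- **Inferred CNV** — reference-centered, chromosome-wise moving-average
  profiles (inferCNV-style; T cells as internal reference, 0.1 reference
  mean cutoff), exclusion of expression changes shared by epithelial cells
  of all samples (lineage transcription, not genomic change), and a
  per-cell aberration burden.
- **Niche mapping and trajectory** — per-cell `T^INF − T^NOD` score
  difference, cluster ranking into Low/Med/High infiltrative groups, a
  centroid-MST pseudotime rooted in the lowest cluster, Moran's I
  autocorrelation screening (cutoff 0.1) on the cell kNN graph, and the
  overlap with known secreted CAF activators (TGF-β superfamily, PDGFs,
  EGF family, FGFs, hedgehog).

A synthetic-data module generates both modalities with planted ground truth
(negative-binomial counts, a latent nodular→infiltrative coordinate driving
two antagonistic programs, patient-specific CNV segments, contamination
mixtures with planted morphology fold-changes, probe-level dispersion and
aberrant probes), so every stage is testable as a parameter-recovery
problem.

## Worked example

```r
library(spatialniche)
run <- run_all(pipeline_config("bcc_run", seed = 5))
print(run)
#> niche_run (seed 5):
#>   cells retained: 1643
#>   tumor subclusters: 4
#>   signatures (filtered): T^NOD 60, T^INF 60, S^NOD 60, S^INF 60
#>   NOD/INF anticorrelation rho: -0.902
#>   top activator overlap: INHBA
run$niche$ranking
#>   cluster  mean_diff rank label   group
#> 1       2 -0.6006628    1   TC1     Low
#> 2       3 -0.3842487    2   TC2  MedLow
#> 3       4  0.2453489    3   TC3 MedHigh
#> 4       1  0.6680977    4   TC4    High
```

Reading the output: of 1700 simulated cells, 1643 pass QC (the planted
low-quality cells are removed). The DSP morphology DEGs, after
contamination filtering against the single-cell compartment profiles,
recover the four planted 60-gene programs. Tumor subclusters, ranked by
their mean `T^INF − T^NOD` module-score difference and relabeled TC1…TC4,
span the planted infiltrative continuum — the strong negative correlation
(rho ≈ −0.9) between NOD and INF scores is the continuum's signature. The
pseudotime trajectory rooted at TC1 identifies the planted INHBA-like
paracrine driver as the top-autocorrelated CAF activator (Moran's I ≈ 0.12,
above the 0.1 screening cutoff), while the homogeneously expressed
TGFB1-like control does not pass.

Every artifact (cluster tables, DEG tables, signature gene lists with a
per-gene filter decision log, CNV burden, pseudotime, autocorrelation
table) is written under the output directory and listed in
`manifest.json`; a rerun with the same configuration is byte-identical.

A thin CLI wrapper ships in `inst/cli/spatialniche`
(`simulate sc | simulate dsp | pipeline run`).

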