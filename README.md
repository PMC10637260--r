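# scmeta

Contrast two exposure groups — the running example is **smokers vs
never-smokers** — across the cell clusters of a multi-sample single-cell
RNA-seq atlas. The package is aimed at analysts running meta-analyses of
integrated scRNA-seq cohorts who have cluster labels and per-sample clinical
metadata (exposure, age) and want to quantify, per cell type:

1. **Expression diversity (VARIED)** — how much more (or less)
   transcriptionally heterogeneous one group's cells are. Within a cluster
   and group, cells are connected in a complete weighted graph with edge
   distance `d(u, v) = 1 − |r(u, v)|` (Pearson correlation of log-normalized
   profiles, clamped to `[1e-6, 1]`). Each cell's normalized closeness
   centrality

   ```
   C(v) = (n − 1) / Σ_{u≠v} d_sp(v, u)
   ```

   (shortest-path distances `d_sp`) measures how close it sits to the rest
   of its population. The statistic is the difference of group medians of
   `C`, computed over seeded subsamples of 100 cells, reported signed and in
   absolute value, with clusters ranked by `|diff|`.

2. **Age-trend differences (AGED)** — per-gene differences in aging
   trajectories. Each sample's cells in a cluster are averaged into one
   pseudobulk profile; expression is regressed on donor age by OLS per
   group; the slope difference

   ```
   Δ = slope(smoker) − slope(never)    [expression units / year]
   ```

   is tabulated per gene × cluster, and genes with `|Δ|` strictly above a
   threshold (default 0.5) in ≥ 3 clusters are selected for a heat-map-ready
   table.

Around these sit the standard stages: a CellRanger-style MTX triplet reader,
QC filtering (`n_features > 1000` and `percent_mt < 20`, both strict),
log1p-CP10K normalization, control-binned gene-set module scoring, Welch
contrasts of per-sample cell composition and per-gene expression, a
deterministic end-to-end pipeline (`run_pipeline()`), and a synthetic atlas
generator (`generate_atlas()`) that plants known heterogeneity contrasts,
age slopes and low-quality cells, recording every planted effect as ground
truth.

## Worked example

Simulate a small atlas in which cluster1's smokers are markedly more
heterogeneous (heterogeneity SD 0.7 vs 0.2) and gene `GENE0101` gains
expression with age in smokers (+0.04 units/year) but not in never-smokers
(−0.01):

```r
library(scmeta)

het <- matrix(0.3, 3, 2); het[1, ] <- c(0.7, 0.2)
cfg <- sim_config(n_samples_per_group = 6, n_clusters = 3,
                  cells_per_sample_per_cluster = 40, n_genes = 800,
                  mito_gene_count = 8, heterogeneity_sd = het,
                  aged_genes = list(list(gene = "GENE0101",
                                         clusters = paste0("cluster", 1:3),
                                         slope_group1 = 0.04,
                                         slope_group2 = -0.01,
                                         baseline = 2.5)),
                  seed = 7)
atlas <- generate_atlas(cfg)
qc <- compute_qc(atlas$counts)
filtered <- filter_cells(atlas$counts, qc, min_features = 300, max_mito = 25)
expr <- normalize_counts(filtered)
meta <- cell_metadata(atlas)
meta <- meta[meta$cell_id %in% colnames(expr), ]

va <- varied_analysis(expr, meta, groups = c("smoker", "never"),
                      subsample_size = 100, n_reps = 10, min_cells = 100,
                      seed = 42)
print(va$table, digits = 3)
#>    cluster median_smoker median_never     diff abs_diff welch_t  welch_p
#> 1 cluster1          1.21         1.30 -0.09292  0.09292 -19.370 7.57e-74
#> 2 cluster2          1.27         1.29 -0.02384  0.02384  -7.464 1.25e-13
#> 3 cluster3          1.28         1.28  0.00219  0.00219   0.694 4.88e-01
```

The planted cluster tops the ranking with a *negative* difference: more
heterogeneous smoker cells are less correlated, sit farther apart in the
graph, and so have lower closeness. (Medians above 1 are expected — with
distances below 1 the `(n − 1)`-normalized closeness exceeds 1.)

```r
ag <- aged_analysis(expr, meta, atlas$sample_meta,
                    groups = c("smoker", "never"),
                    delta_threshold = 0.03, min_clusters = 2)
subset(ag$deltas, gene == "GENE0101")
#>       cluster     gene slope_smoker slope_never ... delta significance
#>  109 cluster1 GENE0101        0.040     -0.0176 ... 0.058  smoker-only
#>  909 cluster2 GENE0101        0.044     -0.0049 ... 0.049  smoker-only
#> 1709 cluster3 GENE0101        0.044      0.0051 ... 0.039  smoker-only
ag$selection$genes
#> [1] "GENE0101"
```

The estimated per-group slopes bracket the planted +0.04/−0.01, the slope
difference Δ ≈ 0.05 = 0.04 − (−0.01) is recovered in all three clusters, and
the selection rule returns exactly the planted gene. (The `delta_threshold`
here is scaled to the planted effect; the 0.5 default targets much stronger
age trends.)

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages —
simulate → QC → normalize → VARIED → AGED → module scores → composition and
gene contrasts — writing TSV tables plus a `manifest.json`; the same
configuration always produces a byte-identical bundle.

See the vignette (`vignettes/expression-diversity-and-aging.Rmd`) for the
model details, parameter rationale, and known limitations (in particular,
why the Welch p-values attached to centrality contrasts should be read as
descriptive, not calibrated).

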