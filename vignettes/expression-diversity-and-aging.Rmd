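---
title: "Expression diversity and age-trend contrasts in multi-sample single-cell atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression diversity and age-trend contrasts in multi-sample single-cell atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmeta)
```

## What the package computes

`scmeta` implements two statistics for contrasting exposure groups (the
running example is smokers vs never-smokers) across the cell clusters of a
multi-sample single-cell RNA-seq atlas, plus the supporting stages they sit
in: quality control, log-normalization, control-binned gene-set module
scoring, Welch contrasts of cell composition and gene expression, and a
ground-truthed synthetic atlas generator used to validate all of it.

**Expression diversity (VARIED).** Within one cluster and one exposure
group, draw a subsample of cells, compute all pairwise Pearson correlations
`r` of their log-normalized expression profiles, and connect every cell pair
with an edge of length `d = 1 - |r|`. Tightly co-regulated (homogeneous)
populations give short edges; heterogeneous populations give long ones.
Each cell's *normalized closeness centrality*,

    C(v) = (n - 1) / sum_u d_sp(v, u),

with `d_sp` the shortest-path distance, is then a per-cell summary of how
close that cell sits to the rest of the population; the
group median of `C` summarizes the cluster's expression homogeneity, and the
difference of group medians (exposed minus unexposed, reported signed and in
absolute value) is the per-cluster diversity statistic. Clusters are ranked
by the absolute difference.

**Age-trend differences (AGED).** For one cluster, average the
log-normalized expression of each sample's cells (one pseudobulk profile per
donor, so the donor carries the age), then regress expression on donor age
by ordinary least squares separately in each exposure group. The quantity of
interest is the slope difference per gene,

    delta = slope(exposed) - slope(unexposed)   [expression units / year],

with per-group two-sided slope t-tests at p < 0.05 feeding a four-level
significance class. Genes with `|delta|` strictly above a threshold (default
0.5) in at least `min_clusters` clusters (default 3) are selected for the
heat-map export.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_features` | 1000 | genes/cell | strict lower bound on detected genes; cells at exactly 1000 are removed |
| `max_mito` | 20 | % of counts | strict upper bound on mitochondrial fraction; 20% exactly is removed |
| `scale_factor` | 10,000 | counts/cell | CP10K library-size target before `log1p` |
| `subsample_size` | 100 | cells | size of each VARIED subsample; medians stabilize near 100 cells |
| `n_reps` | 20 | subsamples | replicates pooled per group |
| `min_cells` | 100 | cells | below this a cluster's result is flagged `sufficient = FALSE`, not dropped |
| `min_distance` | 1e-6 | distance | lower clamp on `1 - |r|`; keeps duplicated cells from creating zero-length edges |
| `delta_threshold` | 0.5 | units/year | strict cut on the slope difference |
| `min_clusters` | 3 | clusters | clusters that must exceed the cut |
| `min_samples` | 3 | samples/group | smallest group for which a slope t-test is attempted |
| `alpha` | 0.05 | -- | significance threshold throughout |
| `n_bins` / `n_ctrl` | 24 / 100 | -- | module-score control binning, the conventional defaults of this algorithm |

## Design choices where the design was open

* **Normalization.** Counts are log1p-CP10K normalized. Regularized
  negative-binomial residual normalization (SCTransform-style) is a separate
  method with its own model; plain log-normalization preserves everything
  the centrality and slope statistics need (zeros map to zero, monotone in
  counts) and keeps the pipeline dependency-free and exactly reproducible.
* **Graph construction.** The correlation matrix becomes a *complete*
  weighted graph -- no edge thresholding -- so closeness is well defined
  without ad-hoc sparsification. Distances are clamped to
  `[1e-6, 1]`. Note that with distances below 1 the `(n - 1)`-normalized
  closeness can exceed 1; that is the intended convention.
* **Correlation flavor.** Pearson on log-normalized expression, with
  Spearman available via `method = "spearman"`. Genes with zero variance
  across a subsample are excluded before correlating (an all-zero gene
  carries no information about cell-cell similarity but would otherwise
  shift both profiles' means).
* **Subsampling protocol.** Per group, `n_reps` seeded subsamples without
  replacement, centralities pooled. Replicate seeds are shared across
  groups, so two identical groups produce a difference of exactly zero and
  swapping group labels negates the difference exactly. A group at or below
  the subsample size is used in full as a single replicate.
* **Regression unit.** Pseudobulk per sample, not per cell: the donor
  carries the age, so sample-level points are the only reading in which the
  regression's independence assumption is even approximately right.
  Per-cell regression would pseudo-replicate each donor hundreds of times.
* **Signed vs absolute selection.** The slope-difference table stores signed
  `delta`; selection thresholds `|delta|` by default (`use_abs = FALSE`
  switches to the signed reading).
* **Multiple testing.** Per-gene slope p-values are reported unadjusted at
  `p < 0.05`, feeding the significance classes; the selection rule itself is
  an effect-size rule, not a p-value rule.

## The synthetic atlas generator

The generator emulates the statistical structure the two statistics assume,
with every planted effect recorded in a `ground_truth` object:

* counts are negative binomial with a shared dispersion around
  cluster-specific mean programs (a seeded subset of genes elevated
  `program_strength`-fold);
* *heterogeneity* is a per-cell lognormal factor (parameterized to mean 1)
  scaling the cluster's program genes. A scalar multiple of a whole
  expression profile would leave Pearson correlations unchanged, which is
  why the factor acts on the program subset only: larger `heterogeneity_sd`
  then lowers pairwise cell-cell correlation, giving a tunable, directional
  ground truth for the centrality contrast
  (`ground_truth$centrality_direction`);
* *age effects* are planted on the scale the regression sees: for a target
  log-normalized mean `t(age) = baseline + slope * (age - mid_age)`, the
  generator numerically inverts `E[log1p(X * 1e4 / total)] = t` for the
  negative-binomial mean. Planting the naive `log1p(mean)` instead would
  make the planted slopes unrecoverable: `log1p` is concave, so its
  downward bias grows at noisy low counts and distorts the very slope being
  planted. Targets must stay within `[0, 8.5]` log-units, the representable
  range under CP10K normalization;
* *low-quality cells* (shallow, mitochondria-rich) are planted at a
  configurable rate so the QC filter has something real to remove;
* donor ages are uniform over `age_range` (whole years), optionally offset
  in one group to mimic cohort age imbalance; mitochondrial genes carry a
  `MT-` prefix and an elevated mean, as in real cells.

What the generator does **not** emulate: batch effects between cohorts,
doublets, ambient RNA, gene-level mean heterogeneity beyond the program
structure, or any particular published cohort. Passing tests on this
generator therefore show that the statistics recover what they claim to
measure under their own assumptions -- not that those assumptions hold in
any given real atlas.

## Numerical conventions and degenerate inputs

* A cell with zero total counts gets `percent_mt = 0` and is removable by
  the feature filter; normalization refuses zero-total cells outright.
* Both QC inequalities are strict; boundary cells are removed.
* A constant gene in a regression gets slope 0 and p = 1; an exact nonzero
  line gets p = 0. Two constant, equal samples give Welch `t = 0, p = 1`;
  constant unequal samples give `t = +/-Inf, p = 0`.
* Module-score bins are near-equal rank bins (sizes differ by at most one),
  ties broken by stable gene order for determinism; a bin at or below
  `n_ctrl` genes is used in full, which makes small examples exactly
  reproducible by hand.
* All randomness is seeded; the pipeline writes no timestamps, so one
  configuration yields a byte-identical output bundle.

## Problem sizes used in validation

The test-suite and acceptance-script study conditions are scaled to run on a
laptop-class single core: correlation graphs up to 150 cells per group,
convergence profiled at subsample sizes 25 vs 100 with 10 replicates,
slope-difference recovery at 40 samples per group with planted slopes
+0.8 / -0.2 units/year over ages 55-65 at low dispersion noise, null
calibration over hundreds to a thousand simulated two-group atlases, and an
end-to-end default atlas of 20 samples x 5 clusters x 2,000 genes
(3,000 cells).

## Known limitations

* **The Welch p-value on centralities is anticonservative.** Closeness
  values computed on one correlation graph are positively correlated across
  cells (each pairwise distance feeds two cells' centralities, and the
  graph-wide level fluctuates between realizations), while the Welch test
  treats them as independent. Under an exchangeable null the rejection rate
  at `alpha = 0.05` is therefore well above nominal -- the acceptance
  script's `varied_null_rejection_rate` quantifies it on simulated data,
  and the signed difference remains correctly centered at zero
  (`varied_null_median_diff`). Treat the per-cluster Welch p-values as a
  descriptive ordering device, not calibrated inference; the ranking by
  absolute median difference, the directional recovery, and the convergence
  diagnostics are unaffected.
* Closeness medians need on the order of 100 cells per group to stabilize;
  smaller clusters are flagged `sufficient = FALSE` and should be read with
  caution.
* The slope-difference selection threshold is in expression-units/year and
  interacts with the normalization scale; on other normalizations the
  default 0.5 is not transferable.
* Pseudobulk regression assumes one age per sample and at least
  `min_samples` samples per group per cluster; clusters failing this are
  skipped and reported, not silently dropped.
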