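make_aged_atlas <- function(slope_smoker = 0.10, slope_never = -0.05,
                            n_samples = 10, cells = 15, seed = 1,
                            clusters = "cluster1", n_clusters = 2) {
  cfg <- sim_config(n_samples_per_group = n_samples, n_clusters = n_clusters,
                    cells_per_sample_per_cluster = cells, n_genes = 150,
                    mito_gene_count = 2, age_range = c(50, 70),
                    nb_dispersion = 50, heterogeneity_sd = 0.05,
                    low_quality_fraction = 0,
                    aged_genes = list(list(gene = "GENE0020",
                                           clusters = clusters,
                                           slope_group1 = slope_smoker,
                                           slope_group2 = slope_never,
                                           baseline = 3)),
                    seed = seed)
  atlas <- generate_atlas(cfg)
  list(atlas = atlas, expr = normalize_counts(atlas$counts),
       meta = cell_metadata(atlas))
}

test_that("pseudobulk rows are per-sample means over the cluster's cells", {
  e <- toy_expr(as.numeric(1:12), 4, 3)
  meta <- data.frame(cell_id = colnames(e),
                     sample_id = c("s1", "s1", "s2"),
                     cluster = "k1")
  pb <- pseudobulk(e, meta, "k1")
  # s1 averages cells 1 and 2; s2 is the single cell 3 verbatim
  expect_equal(pb$means["s1", ], rowMeans(e[, 1:2]), tolerance = 1e-12)
  expect_equal(pb$means["s2", ], e[, 3], tolerance = 1e-12)
  expect_equal(unname(pb$n_cells), c(2L, 1L))
  # a sample with no cells in the cluster is absent
  meta$cluster[3] <- "k2"
  pb <- pseudobulk(e, meta, "k1")
  expect_equal(rownames(pb$means), "s1")
  expect_error(pseudobulk(e, meta, "k9"), "no cells")
})

test_that("age regression reproduces exact lines and flat responses", {
  values <- cbind(line = c(22, 27, 32), flat = c(5, 5, 5))
  fit <- fit_age_regression(values, ages = c(40, 50, 60))
  expect_equal(fit$slope, c(0.5, 0))
  expect_equal(fit$intercept[1], 2)
  expect_equal(fit$p[2], 1)
  expect_equal(fit$p[1], 0)  # exact nonzero line: zero residual
  expect_error(fit_age_regression(values[1:2, ], c(40, 50)), "at least 3")
  expect_error(fit_age_regression(values, c(50, 50, 50), group = "smoker"),
               "identical.*smoker")
})

test_that("vectorized OLS agrees with the normal-equations oracle", {
  withr::with_seed(17, {
    n <- 30
    ages <- runif(n, 35, 85)
    values <- sapply(1:25, function(j) {
      rnorm(1) + rnorm(1, sd = 0.05) * ages + rnorm(n, sd = 0.3)
    })
    colnames(values) <- paste0("g", 1:25)
  })
  fit <- fit_age_regression(values, ages)
  for (j in 1:25) {
    o <- ols_oracle(ages, values[, j])
    expect_equal(fit$slope[j], unname(o$slope), tolerance = 1e-10)
    expect_equal(fit$intercept[j], unname(o$intercept), tolerance = 1e-10)
    expect_equal(fit$se[j], unname(o$se), tolerance = 1e-10)
    expect_equal(fit$p[j], unname(o$p), tolerance = 1e-10)
  }
})

test_that("slope differences and significance classes follow the contracts", {
  fit1 <- data.frame(gene = c("a", "b"), slope = c(1.0, 0.2),
                     intercept = 0, se = 0.1, t = 1, p = c(0.01, 0.2), n = 10)
  fit2 <- data.frame(gene = c("b", "a"), slope = c(-0.3, 0.5),
                     intercept = 0, se = 0.1, t = 1, p = c(0.03, 0.6), n = 10)
  d <- aged_delta(fit1, fit2, groups = c("smoker", "never"))
  expect_equal(d$delta[d$gene == "a"], 1.0 - 0.5)
  expect_equal(d$delta[d$gene == "b"], 0.2 - (-0.3))
  expect_equal(d$significance[d$gene == "a"], "smoker-only")
  expect_equal(d$significance[d$gene == "b"], "never-only")
  # identical fits: all deltas zero, class reflects shared p-values
  d0 <- aged_delta(fit1, fit1)
  expect_true(all(d0$delta == 0))
  expect_error(aged_delta(fit1, fit1[1, ]), "different gene sets")
})

test_that("group swap negates every delta and leaves |delta| selection invariant", {
  dat <- make_aged_atlas(seed = 23)
  a <- aged_cluster(dat$expr, dat$meta, dat$atlas$sample_meta, "cluster1",
                    groups = c("smoker", "never"))
  b <- aged_cluster(dat$expr, dat$meta, dat$atlas$sample_meta, "cluster1",
                    groups = c("never", "smoker"))
  b <- b[match(a$gene, b$gene), ]
  expect_equal(b$delta, -a$delta, tolerance = 1e-12)
  ta <- a[, c("gene", "cluster", "delta")]
  tb <- b[, c("gene", "cluster", "delta")]
  sa <- select_aged_genes(ta, delta_threshold = 0.02, min_clusters = 1)
  sb <- select_aged_genes(tb, delta_threshold = 0.02, min_clusters = 1)
  expect_setequal(sa$genes, sb$genes)
})

test_that("planted slopes are recovered from pseudobulk regressions", {
  dat <- make_aged_atlas(slope_smoker = 0.10, slope_never = -0.05,
                         n_samples = 20, cells = 25, seed = 29)
  res <- aged_cluster(dat$expr, dat$meta, dat$atlas$sample_meta, "cluster1",
                      groups = c("smoker", "never"))
  row <- res[res$gene == "GENE0020", ]
  truth <- dat$atlas$ground_truth$true_delta$delta  # 0.15
  expect_lt(abs(row$delta - truth), 0.25 * abs(truth))
  expect_equal(row$significance, "both")
})

test_that("gene selection applies the strict threshold-and-count rule", {
  tab <- data.frame(
    gene = rep(c("hit3", "hit2", "neg", "edge"), each = 4),
    cluster = rep(paste0("k", 1:4), times = 4),
    delta = c(0.6, 0.7, 0.8, 0.1,      # hit3: 3 clusters over
              0.6, 0.6, 0.4, 0.2,      # hit2: only 2 over
              -0.9, -0.8, -0.7, 0.0,   # neg: |delta| over in 3
              0.5, 0.5, 0.5, 0.5))     # edge: exactly at threshold -> never over
  sel <- select_aged_genes(tab, delta_threshold = 0.5, min_clusters = 3)
  expect_setequal(sel$genes, c("hit3", "neg"))
  expect_equal(unname(sel$counts[c("hit3", "neg")]), c(3L, 3L))
  expect_equal(sel$delta_wide["neg", "k1"], -0.9)
  # signed thresholding excludes the negative-delta gene
  sel_signed <- select_aged_genes(tab, delta_threshold = 0.5,
                                  min_clusters = 3, use_abs = FALSE)
  expect_equal(sel_signed$genes, "hit3")
  # fewer clusters than required: warning and empty selection
  expect_warning(
    empty <- select_aged_genes(tab[tab$cluster %in% c("k1", "k2"), ],
                               min_clusters = 3),
    "empty selection")
  expect_length(empty$genes, 0)
})

test_that("random delta tables match a brute-force count-and-filter scan", {
  withr::with_seed(41, {
    tab <- expand.grid(gene = paste0("g", 1:40), cluster = paste0("k", 1:6),
                       stringsAsFactors = FALSE)
    tab$delta <- round(runif(nrow(tab), -1, 1), 2)
  })
  sel <- select_aged_genes(tab, delta_threshold = 0.5, min_clusters = 3)
  brute <- character(0)
  for (g in unique(tab$gene)) {
    n_over <- 0
    for (k in unique(tab$cluster)) {
      d <- tab$delta[tab$gene == g & tab$cluster == k]
      if (abs(d) > 0.5) n_over <- n_over + 1
    }
    if (n_over >= 3) brute <- c(brute, g)
  }
  expect_setequal(sel$genes, brute)
})

test_that("aged_analysis stacks clusters and skips infeasible ones", {
  dat <- make_aged_atlas(seed = 37, clusters = c("cluster1", "cluster2"),
                         n_clusters = 2)
  res <- aged_analysis(dat$expr, dat$meta, dat$atlas$sample_meta,
                       groups = c("smoker", "never"),
                       delta_threshold = 0.06, min_clusters = 2)
  expect_setequal(unique(res$deltas$cluster), c("cluster1", "cluster2"))
  expect_true("GENE0020" %in% res$selection$genes)
  # a group with too few samples in a cluster is skipped with a warning
  meta_cut <- dat$meta[!(dat$meta$cluster == "cluster2" &
                           dat$meta$sample_id %in%
                           dat$atlas$sample_meta$sample_id[1:8]), ]
  expect_warning(
    res2 <- aged_analysis(dat$expr, meta_cut, dat$atlas$sample_meta,
                          groups = c("smoker", "never"),
                          min_samples = 3, min_clusters = 1),
    "skipping cluster 'cluster2'")
  expect_equal(res2$skipped, "cluster2")
})
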