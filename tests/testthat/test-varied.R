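# small helper: expression + metadata for a two-group cluster
make_group_data <- function(n_genes = 120, n_per_group = 40, het = c(0, 0),
                            seed = 1) {
  cfg <- sim_config(n_samples_per_group = 1, n_clusters = 1,
                    cells_per_sample_per_cluster = n_per_group,
                    n_genes = n_genes, mito_gene_count = 2,
                    heterogeneity_sd = het, program_fraction = 0.3,
                    low_quality_fraction = 0, seed = seed)
  atlas <- generate_atlas(cfg)
  expr <- normalize_counts(atlas$counts)
  meta <- cell_metadata(atlas)
  list(expr = expr, meta = meta, atlas = atlas)
}

test_that("correlation distances follow the |Pearson r| contract", {
  # perfectly correlated, anti-correlated, and r = 0.5 cell pairs
  e <- toy_expr(c(1, 2, 3, 2, 4, 6), 3, 2)
  g <- correlation_distance_graph(e)
  expect_equal(unname(g$distances[1, 2]), 1e-6)      # r = 1, clamped

  e <- toy_expr(c(1, 2, 3, 3, 2, 1), 3, 2)
  g <- correlation_distance_graph(e)
  expect_equal(unname(g$distances[1, 2]), 1e-6)      # r = -1, |r| = 1

  e <- toy_expr(c(1, 2, 3, 3, 5, 4), 3, 2)
  r <- sum(scale(c(1, 2, 3)) * scale(c(3, 5, 4))) / 2  # hand Pearson: 0.5
  expect_equal(r, 0.5)
  g <- correlation_distance_graph(e)
  expect_equal(unname(g$distances[1, 2]), 0.5)
  expect_equal(diag(g$distances), rep(0, 2), ignore_attr = TRUE)

  # a gene constant across the subsample is excluded before correlating
  e <- toy_expr(c(1, 2, 3, 1, 3, 2), 3, 2)  # gene 1 constant; rest r = -1
  g <- correlation_distance_graph(e)
  expect_equal(unname(g$distances[1, 2]), 1e-6)

  expect_error(correlation_distance_graph(toy_expr(1:3, 3, 1)), "2 cells")
  # constant genes dropped; fewer than 2 informative genes left
  e <- toy_expr(c(5, 5, 1, 5, 5, 2), 3, 2)
  expect_error(correlation_distance_graph(e), "nonzero variance")
})

test_that("closeness matches textbook values on simple graphs", {
  # complete graph with unit distances: every centrality is 1
  d <- matrix(1, 4, 4); diag(d) <- 0
  expect_equal(unname(normalized_closeness(cluster_graph(d))), rep(1, 4))

  # path a-b-c with unit edges (0 = absent edge): C(b)=1, C(a)=C(c)=2/3
  d <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(unname(normalized_closeness(cluster_graph(d))),
               c(2 / 3, 1, 2 / 3))
})

test_that("closeness equals the Floyd-Warshall oracle and scales correctly", {
  withr::with_seed(14, {
    for (n in c(10, 30)) {
      d <- rand_dist_matrix(n)
      cg <- cluster_graph(d)
      impl <- unname(normalized_closeness(cg))
      expect_equal(impl, unname(closeness_fw(d)), tolerance = 1e-10)
      # multiplying every distance by k divides every closeness by k
      k <- 2.5
      expect_equal(unname(normalized_closeness(cluster_graph(k * d))),
                   impl / k, tolerance = 1e-10)
    }
  })
  expect_error(normalized_closeness(cluster_graph(matrix(0, 1, 1))), "2 nodes")
  # disconnected graph rejected
  d <- matrix(0, 4, 4); d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  expect_error(normalized_closeness(cluster_graph(d)), "not connected")
})

test_that("contrasting a group against itself gives exactly zero difference", {
  dat <- make_group_data(n_per_group = 30, seed = 4)
  # relabel: both groups point at the same 30 cells (duplicated columns)
  cells <- dat$meta$cell_id[dat$meta$smoking_status == "smoker"]
  expr2 <- cbind(dat$expr[, cells], dat$expr[, cells])
  colnames(expr2) <- c(paste0(cells, "_a"), paste0(cells, "_b"))
  meta2 <- data.frame(cell_id = colnames(expr2),
                      cluster = "cluster1",
                      smoking_status = rep(c("smoker", "never"), each = 30))
  v <- varied_statistic(expr2, meta2, "cluster1", groups = c("smoker", "never"),
                        subsample_size = 20, n_reps = 4, min_cells = 10,
                        seed = 7)
  expect_identical(v$diff, 0)
  expect_identical(v$welch_t, 0)
  expect_identical(v$welch_p, 1)
})

test_that("swapping the group order negates the difference and keeps |diff|", {
  dat <- make_group_data(het = c(0.8, 0.1), seed = 5)
  a <- varied_statistic(dat$expr, dat$meta, "cluster1",
                        groups = c("smoker", "never"), subsample_size = 25,
                        n_reps = 5, min_cells = 20, seed = 3)
  b <- varied_statistic(dat$expr, dat$meta, "cluster1",
                        groups = c("never", "smoker"), subsample_size = 25,
                        n_reps = 5, min_cells = 20, seed = 3)
  expect_equal(b$diff, -a$diff)
  expect_equal(b$abs_diff, a$abs_diff)
  expect_false(isTRUE(all.equal(a$diff, 0)))
  # higher smoker heterogeneity lowers smoker centrality
  expect_equal(sign(a$diff),
               unname(dat$atlas$ground_truth$centrality_direction["cluster1"]))
})

test_that("results are reproducible from the seed and bookkeeping is correct", {
  dat <- make_group_data(seed = 6)
  a <- varied_statistic(dat$expr, dat$meta, "cluster1",
                        groups = c("smoker", "never"), subsample_size = 25,
                        n_reps = 4, min_cells = 100, seed = 11)
  b <- varied_statistic(dat$expr, dat$meta, "cluster1",
                        groups = c("smoker", "never"), subsample_size = 25,
                        n_reps = 4, min_cells = 100, seed = 11)
  expect_identical(a[setdiff(names(a), "centrality")],
                   b[setdiff(names(b), "centrality")])
  expect_equal(a$centrality, b$centrality)
  # 40 cells per group < min_cells = 100 -> result returned but insufficient
  expect_false(a$sufficient)
  expect_equal(unname(a$n_used), c(40, 40))
  expect_error(varied_statistic(dat$expr, dat$meta, "clusterX"), "not found")
})

test_that("convergence profiling handles degenerate replicate setups", {
  dat <- make_group_data(n_per_group = 30, seed = 9)
  # subsample size equal to the full group: every replicate is identical
  conv <- varied_convergence(dat$expr, dat$meta, "cluster1",
                             groups = c("smoker", "never"), sizes = 30,
                             n_reps = 4, seed = 2)
  expect_equal(conv$sd, c(0, 0))
  # a single replicate: SD undefined, reported as NA
  conv1 <- varied_convergence(dat$expr, dat$meta, "cluster1",
                              groups = c("smoker", "never"), sizes = 15,
                              n_reps = 1, seed = 2)
  expect_true(all(is.na(conv1$sd)))
  # infeasible sizes name the feasible ones
  expect_error(varied_convergence(dat$expr, dat$meta, "cluster1",
                                  sizes = c(15, 500), n_reps = 2),
               "feasible sizes: 15")
})

test_that("clusters are ranked by absolute difference with ties to the data", {
  dat <- make_group_data(seed = 10)
  r1 <- varied_statistic(dat$expr, dat$meta, "cluster1",
                         groups = c("smoker", "never"), subsample_size = 20,
                         n_reps = 3, min_cells = 10, seed = 1)
  r2 <- r1; r2$cluster <- "clusterB"; r2$diff <- 0.3; r2$abs_diff <- 0.3
  r3 <- r1; r3$cluster <- "clusterC"; r3$diff <- -0.1; r3$abs_diff <- 0.1
  tab <- rank_clusters(list(r3, r2, r1))
  expect_equal(tab$cluster[1], "clusterB")
  expect_equal(tab$abs_diff, sort(tab$abs_diff, decreasing = TRUE))
  # single result ranks as itself
  expect_equal(rank_clusters(r1)$cluster, "cluster1")
  # random tables agree with an independent comparison sort
  withr::with_seed(31, {
    fake <- lapply(1:6, function(i) {
      r <- r1; r$cluster <- paste0("k", i)
      r$diff <- runif(1, -1, 1); r$abs_diff <- abs(r$diff); r
    })
  })
  tab <- rank_clusters(fake)
  oracle <- sapply(fake, function(r) r$abs_diff)
  expect_equal(tab$cluster, paste0("k", order(oracle, decreasing = TRUE)))
})
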