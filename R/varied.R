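#' Cell-cell correlation distance graph
#'
#' Builds the complete weighted graph over the cells of one cluster x group
#' subsample. Genes with zero variance across the subsample are dropped, the
#' pairwise Pearson (or Spearman) correlation r is computed across the
#' remaining genes, and the edge distance is `1 - |r|`, clamped off-diagonal
#' to `[min_distance, 1]`. The lower clamp keeps duplicated cells (|r| = 1)
#' from creating zero-length edges.
#'
#' @param expr log-normalized expression (genes x cells) restricted to the
#'   subsample; dense or sparse.
#' @param method correlation flavor, `"pearson"` (default) or `"spearman"`.
#' @param min_distance lower clamp for off-diagonal distances (default 1e-6).
#' @return An object of class `cluster_graph` with elements `nodes` (cell
#'   ids) and `distances` (symmetric matrix, zero diagonal).
#' @export
correlation_distance_graph <- function(expr, method = c("pearson", "spearman"),
                                       min_distance = 1e-6) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) {
    stop("need at least 2 cells to build a correlation graph", call. = FALSE)
  }
  v <- rowMeans(expr^2) - rowMeans(expr)^2
  expr <- expr[v > 1e-12, , drop = FALSE]
  if (nrow(expr) < 2) {
    stop("fewer than 2 genes with nonzero variance in the subsample", call. = FALSE)
  }
  r <- stats::cor(expr, method = method)
  r[!is.finite(r)] <- 0  # a cell constant across the retained genes
  d <- 1 - abs(r)
  d <- pmin(pmax(d, min_distance), 1)
  diag(d) <- 0
  cluster_graph(d, nodes = colnames(expr))
}

#' Construct a cluster graph from a distance matrix
#'
#' @param distances symmetric non-negative matrix with zero diagonal.
#'   Off-diagonal zeros are treated as absent edges, so non-complete graphs
#'   (e.g. paths) can be represented directly.
#' @param nodes node labels; defaults to the matrix row names.
#' @return `cluster_graph` object.
#' @export
cluster_graph <- function(distances, nodes = NULL) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(distances - t(distances))) > 1e-12) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(distances) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  nodes <- nodes %||% rownames(distances) %||%
    paste0("v", seq_len(nrow(distances)))
  dimnames(distances) <- list(nodes, nodes)
  structure(list(nodes = nodes, distances = distances), class = "cluster_graph")
}

#' Normalized closeness centrality
#'
#' For each node v of a connected weighted graph,
#' `C(v) = (n - 1) / sum_u d_sp(v, u)` where `d_sp` is the shortest-path
#' distance under the edge weights. With the `(n - 1)` numerator and
#' distances below 1 the values can exceed 1; that is the intended
#' convention.
#'
#' @param graph a [cluster_graph] (or a plain distance matrix, coerced).
#' @return Named numeric vector of per-node centralities.
#' @export
normalized_closeness <- function(graph) {
  if (!inherits(graph, "cluster_graph")) graph <- cluster_graph(graph)
  n <- length(graph$nodes)
  if (n < 2) stop("closeness needs at least 2 nodes", call. = FALSE)
  ig <- igraph::graph_from_adjacency_matrix(graph$distances,
                                            mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(ig)
  if (any(!is.finite(D))) stop("graph is not connected", call. = FALSE)
  stats::setNames((n - 1) / rowSums(D), graph$nodes)
}

.subsample_centralities <- function(expr_cells, subsample_size, n_reps, seed,
                                    method, min_distance) {
  n <- ncol(expr_cells)
  if (n <= subsample_size) {
    ## a subsample of the full group is the full group: one effective replicate
    g <- correlation_distance_graph(expr_cells, method = method,
                                    min_distance = min_distance)
    return(list(pooled = normalized_closeness(g), n_reps_effective = 1L))
  }
  pooled <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ## replicate seeds are shared across groups so that identical groups draw
    ## identical cell indices (making the self-contrast exactly zero)
    idx <- if (is.null(seed)) {
      sample.int(n, subsample_size)
    } else {
      withr::with_seed(seed + r, sample.int(n, subsample_size))
    }
    g <- correlation_distance_graph(expr_cells[, idx, drop = FALSE],
                                    method = method,
                                    min_distance = min_distance)
    pooled[[r]] <- normalized_closeness(g)
  }
  list(pooled = unlist(pooled, use.names = FALSE), n_reps_effective = n_reps)
}

#' VARIED statistic for one cluster
#'
#' Contrasts the expression diversity of two exposure groups within one
#' cluster. Per group, `n_reps` seeded subsamples of `subsample_size` cells
#' are drawn without replacement (a group at or below the subsample size is
#' used in full, as a single replicate); each subsample yields a correlation
#' graph whose normalized closeness centralities are pooled across
#' replicates. The result reports group medians, their difference
#' (first group minus second), the absolute difference, and a Welch t test
#' between the pooled centrality distributions. `sufficient` is `TRUE` only
#' when both groups have at least `min_cells` cells, reflecting the
#' convergence requirement of roughly 100 cells per group.
#'
#' @param expr log-normalized expression (genes x cells) for the whole atlas.
#' @param metadata per-cell data.frame with `cell_id`, the cluster column and
#'   the group column.
#' @param cluster cluster label to analyze.
#' @param group_field,cluster_field metadata column names.
#' @param groups two group labels, contrast order first minus second;
#'   `NULL` uses the two labels present (sorted).
#' @param subsample_size cells per subsample (default 100).
#' @param n_reps subsamples per group (default 20).
#' @param min_cells sufficiency threshold per group (default 100).
#' @param seed integer seed making the subsampling reproducible.
#' @param method correlation flavor passed to [correlation_distance_graph()].
#' @param min_distance distance clamp passed on.
#' @return An object of class `varied_result`.
#' @export
varied_statistic <- function(expr, metadata, cluster,
                             group_field = "smoking_status",
                             cluster_field = "cluster",
                             groups = NULL,
                             subsample_size = 100, n_reps = 20,
                             min_cells = 100, seed = NULL,
                             method = "pearson", min_distance = 1e-6) {
  .assert_columns(metadata, c("cell_id", group_field, cluster_field))
  in_cluster <- metadata[metadata[[cluster_field]] == cluster, , drop = FALSE]
  if (!nrow(in_cluster)) {
    stop(sprintf("cluster '%s' not found; available: %s", cluster,
                 paste(sort(unique(metadata[[cluster_field]])), collapse = ", ")),
         call. = FALSE)
  }
  groups <- .resolve_groups(in_cluster[[group_field]], groups)
  pooled <- vector("list", 2)
  n_used <- integer(2)
  reps_eff <- integer(2)
  for (i in 1:2) {
    cells <- in_cluster$cell_id[in_cluster[[group_field]] == groups[i]]
    cells <- intersect(cells, colnames(expr))
    if (length(cells) < 2) {
      stop(sprintf("group '%s' has %d cell(s) in cluster '%s'; need at least 2",
                   groups[i], length(cells), cluster), call. = FALSE)
    }
    n_used[i] <- length(cells)
    sub <- .subsample_centralities(expr[, cells, drop = FALSE],
                                   subsample_size, n_reps, seed,
                                   method, min_distance)
    pooled[[i]] <- sub$pooled
    reps_eff[i] <- sub$n_reps_effective
  }
  medians <- vapply(pooled, stats::median, 0)
  names(medians) <- groups
  wt <- welch_t_test(pooled[[1]], pooled[[2]])
  structure(list(cluster = cluster,
                 groups = groups,
                 centrality = stats::setNames(pooled, groups),
                 medians = medians,
                 diff = unname(medians[1] - medians[2]),
                 abs_diff = abs(unname(medians[1] - medians[2])),
                 welch_t = wt$statistic, welch_p = wt$p_value,
                 n_used = stats::setNames(n_used, groups),
                 n_reps = stats::setNames(reps_eff, groups),
                 subsample_size = subsample_size,
                 min_cells = min_cells,
                 sufficient = all(n_used >= min_cells)),
            class = "varied_result")
}

#' @export
print.varied_result <- function(x, ...) {
  cat(sprintf("<varied_result> cluster %s: median %s = %.4f, %s = %.4f, diff = %+.4f (|diff| = %.4f)\n",
              x$cluster, x$groups[1], x$medians[1], x$groups[2], x$medians[2],
              x$diff, x$abs_diff))
  cat(sprintf("  Welch t = %.3f, p = %.3g; n = %d/%d cells%s\n",
              x$welch_t, x$welch_p, x$n_used[1], x$n_used[2],
              if (x$sufficient) "" else sprintf(" (insufficient, < %d)", x$min_cells)))
  invisible(x)
}

#' Convergence of the VARIED median with subsample size
#'
#' For each subsample size and group, draws `n_reps` seeded subsamples,
#' records the median centrality of each replicate, and summarizes the
#' replicate medians and their standard deviation. The replicate SD is
#' expected (but not enforced) to shrink as the subsample size grows; around
#' 100 cells the medians stabilize, which motivates the default
#' `min_cells = 100` sufficiency rule.
#'
#' @inheritParams varied_statistic
#' @param sizes subsample sizes to profile.
#' @param n_reps replicates per size and group.
#' @return data.frame with columns `size`, `group`, `median` (median of the
#'   replicate medians), `sd` (SD of replicate medians; `NA` when
#'   `n_reps < 2`), `n_reps`. Replicate medians are attached as the
#'   `"replicates"` attribute.
#' @export
varied_convergence <- function(expr, metadata, cluster,
                               group_field = "smoking_status",
                               cluster_field = "cluster", groups = NULL,
                               sizes = c(25, 50, 100, 200), n_reps = 10,
                               seed = NULL, method = "pearson",
                               min_distance = 1e-6) {
  .assert_columns(metadata, c("cell_id", group_field, cluster_field))
  in_cluster <- metadata[metadata[[cluster_field]] == cluster, , drop = FALSE]
  if (!nrow(in_cluster)) stop(sprintf("cluster '%s' not found", cluster), call. = FALSE)
  groups <- .resolve_groups(in_cluster[[group_field]], groups)
  cells_by_group <- lapply(groups, function(g) {
    intersect(in_cluster$cell_id[in_cluster[[group_field]] == g], colnames(expr))
  })
  n_min <- min(lengths(cells_by_group))
  if (any(sizes > n_min)) {
    feasible <- sizes[sizes <= n_min]
    stop(sprintf("smallest group has %d cells; feasible sizes: %s", n_min,
                 if (length(feasible)) paste(feasible, collapse = ", ") else "none"),
         call. = FALSE)
  }
  rows <- list()
  reps_store <- list()
  for (size in sizes) {
    for (i in 1:2) {
      cells <- cells_by_group[[i]]
      meds <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        idx <- if (is.null(seed)) {
          sample.int(length(cells), size)
        } else {
          withr::with_seed(seed + 1000L * match(size, sizes) + r,
                           sample.int(length(cells), size))
        }
        g <- correlation_distance_graph(expr[, cells[idx], drop = FALSE],
                                        method = method,
                                        min_distance = min_distance)
        meds[r] <- stats::median(normalized_closeness(g))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, group = groups[i],
        median = stats::median(meds),
        sd = if (n_reps >= 2) stats::sd(meds) else NA_real_,
        n_reps = n_reps, stringsAsFactors = FALSE)
      reps_store[[paste(size, groups[i], sep = ":")]] <- meds
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- reps_store
  out
}

#' Rank clusters by absolute centrality difference
#'
#' @param results list of [varied_statistic()] results (or a single result).
#' @return data.frame sorted by `abs_diff` descending; clusters below the
#'   cell-sufficiency threshold are flagged in `sufficient`, not dropped.
#' @export
rank_clusters <- function(results) {
  if (inherits(results, "varied_result")) results <- list(results)
  if (!length(results)) stop("no results to rank", call. = FALSE)
  rows <- lapply(results, function(r) {
    data.frame(cluster = r$cluster,
               median_group1 = unname(r$medians[1]),
               median_group2 = unname(r$medians[2]),
               diff = r$diff, abs_diff = r$abs_diff,
               welch_t = r$welch_t, welch_p = r$welch_p,
               n_group1 = unname(r$n_used[1]), n_group2 = unname(r$n_used[2]),
               sufficient = r$sufficient, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  groups <- results[[1]]$groups
  names(out)[names(out) == "median_group1"] <- paste0("median_", groups[1])
  names(out)[names(out) == "median_group2"] <- paste0("median_", groups[2])
  names(out)[names(out) == "n_group1"] <- paste0("n_", groups[1])
  names(out)[names(out) == "n_group2"] <- paste0("n_", groups[2])
  out <- out[order(-out$abs_diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' VARIED analysis across clusters
#'
#' Runs [varied_statistic()] for every requested cluster and returns the
#' per-cluster results together with the ranked summary table.
#'
#' @inheritParams varied_statistic
#' @param clusters clusters to analyze; `NULL` means all clusters in the
#'   metadata (sorted).
#' @return list with `results` (named list of `varied_result`) and `table`
#'   (from [rank_clusters()]).
#' @export
varied_analysis <- function(expr, metadata, clusters = NULL,
                            group_field = "smoking_status",
                            cluster_field = "cluster", groups = NULL,
                            subsample_size = 100, n_reps = 20,
                            min_cells = 100, seed = NULL,
                            method = "pearson", min_distance = 1e-6) {
  clusters <- clusters %||% sort(unique(metadata[[cluster_field]]))
  results <- lapply(clusters, function(k) {
    varied_statistic(expr, metadata, k, group_field = group_field,
                     cluster_field = cluster_field, groups = groups,
                     subsample_size = subsample_size, n_reps = n_reps,
                     min_cells = min_cells, seed = seed, method = method,
                     min_distance = min_distance)
  })
  names(results) <- clusters
  list(results = results, table = rank_clusters(results))
}
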