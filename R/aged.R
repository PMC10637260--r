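#' Per-sample pseudobulk expression for one cluster
#'
#' Averages the log-normalized expression of each sample's cells within one
#' cluster, yielding one profile per sample. Samples contributing no cells to
#' the cluster are absent from the result.
#'
#' @param expr log-normalized expression (genes x cells).
#' @param metadata per-cell data.frame with `cell_id`, `sample_id` and the
#'   cluster column.
#' @param cluster cluster label.
#' @param cluster_field metadata column holding cluster labels.
#' @return Object of class `pseudobulk`: list with `cluster`, `means`
#'   (samples x genes matrix), `n_cells` (named per sample).
#' @export
pseudobulk <- function(expr, metadata, cluster, cluster_field = "cluster") {
  .assert_columns(metadata, c("cell_id", "sample_id", cluster_field))
  sub <- metadata[metadata[[cluster_field]] == cluster, , drop = FALSE]
  sub <- sub[sub$cell_id %in% colnames(expr), , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("no cells found for cluster '%s'", cluster), call. = FALSE)
  }
  f <- factor(sub$sample_id, levels = unique(sub$sample_id))
  ## genes x samples via a sparse indicator carrying 1/n_cells per sample
  n_cells <- as.integer(table(f)[levels(f)])
  ind <- Matrix::sparseMatrix(i = match(sub$cell_id, colnames(expr))[order(f)],
                              j = as.integer(sort(f)),
                              x = rep(1 / n_cells, n_cells),
                              dims = c(ncol(expr), nlevels(f)))
  means <- t(as.matrix(expr %*% ind))
  dimnames(means) <- list(levels(f), rownames(expr))
  structure(list(cluster = cluster, means = means,
                 n_cells = stats::setNames(n_cells, levels(f))),
            class = "pseudobulk")
}

#' Per-gene ordinary least-squares regression of expression on age
#'
#' Fits, for each gene, `expression = intercept + slope * age` by OLS over
#' the samples of one group and tests `slope = 0` with a two-sided t test on
#' `n - 2` degrees of freedom. Genes with zero expression variance get slope
#' 0 and p = 1; a nonzero slope with an exact fit gets p = 0.
#'
#' @param values samples x genes matrix (e.g. `pseudobulk()$means` restricted
#'   to one group's samples).
#' @param ages numeric donor ages aligned to the rows of `values`.
#' @param group optional label used in error messages.
#' @return data.frame with columns `gene`, `slope`, `intercept`, `se`, `t`,
#'   `p`, `n`.
#' @export
fit_age_regression <- function(values, ages, group = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(ages) != n) {
    stop("`ages` must have one entry per sample row", call. = FALSE)
  }
  if (n < 3) {
    stop(sprintf("need at least 3 samples%s to fit an age regression, got %d",
                 if (is.null(group)) "" else sprintf(" in group '%s'", group), n),
         call. = FALSE)
  }
  if (length(unique(ages)) < 2) {
    stop(sprintf("all ages are identical%s; the design is degenerate",
                 if (is.null(group)) "" else sprintf(" in group '%s'", group)),
         call. = FALSE)
  }
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  slopes <- as.numeric(crossprod(xc, values)) / sxx
  intercepts <- colMeans(values) - slopes * mean(ages)
  fitted <- outer(ages, slopes) + rep(intercepts, each = n)
  rss <- colSums((values - fitted)^2)
  gene_var <- colSums((values - rep(colMeans(values), each = n))^2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t_stat <- ifelse(se > 0, slopes / se, ifelse(slopes == 0, 0, sign(slopes) * Inf))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  ## zero-variance genes: flat response by definition
  flat <- gene_var < 1e-24
  slopes[flat] <- 0; t_stat[flat] <- 0; p[flat] <- 1
  p[!flat & !is.finite(t_stat)] <- 0
  data.frame(gene = colnames(values) %||% paste0("g", seq_along(slopes)),
             slope = slopes, intercept = intercepts, se = se,
             t = t_stat, p = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Slope differences between exposure groups for one cluster
#'
#' Aligns two per-group fits from [fit_age_regression()] over the same gene
#' set and reports `delta = slope_group1 - slope_group2` along with a
#' per-gene significance class at `p < alpha` in each group.
#'
#' @param fit_group1,fit_group2 data.frames from [fit_age_regression()].
#' @param groups labels for the two fits (first minus second).
#' @param alpha per-group significance cut (default 0.05).
#' @return data.frame with per-gene slopes, p-values, `delta`, and
#'   `significance` in `both`, `<group1>-only`, `<group2>-only`, `neither`.
#' @export
aged_delta <- function(fit_group1, fit_group2,
                       groups = c("smoker", "never"), alpha = 0.05) {
  if (!setequal(fit_group1$gene, fit_group2$gene) ||
      nrow(fit_group1) != nrow(fit_group2)) {
    stop("the two fits cover different gene sets and cannot be aligned",
         call. = FALSE)
  }
  fit_group2 <- fit_group2[match(fit_group1$gene, fit_group2$gene), ]
  sig1 <- fit_group1$p < alpha
  sig2 <- fit_group2$p < alpha
  significance <- ifelse(sig1 & sig2, "both",
                  ifelse(sig1, paste0(groups[1], "-only"),
                  ifelse(sig2, paste0(groups[2], "-only"), "neither")))
  out <- data.frame(gene = fit_group1$gene,
                    slope_group1 = fit_group1$slope,
                    slope_group2 = fit_group2$slope,
                    intercept_group1 = fit_group1$intercept,
                    intercept_group2 = fit_group2$intercept,
                    p_group1 = fit_group1$p,
                    p_group2 = fit_group2$p,
                    delta = fit_group1$slope - fit_group2$slope,
                    significance = significance,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out) <- sub("group1", groups[1], names(out))
  names(out) <- sub("group2", groups[2], names(out))
  out
}

#' Age-slope contrast for one cluster
#'
#' Convenience wrapper: pseudobulk the cluster, split samples by exposure
#' group, fit the per-group age regressions and return the aligned
#' slope-difference table with the cluster label attached.
#'
#' @inheritParams pseudobulk
#' @param sample_meta data.frame with `sample_id`, the group column and `age`.
#' @param group_field sample metadata column holding group labels.
#' @param groups two group labels (contrast order); `NULL` uses the two
#'   present.
#' @param min_samples minimum samples per group for a fit (default 3).
#' @param alpha per-group significance cut.
#' @return data.frame as [aged_delta()] plus a `cluster` column.
#' @export
aged_cluster <- function(expr, metadata, sample_meta, cluster,
                         cluster_field = "cluster",
                         group_field = "smoking_status", groups = NULL,
                         min_samples = 3, alpha = 0.05) {
  .assert_columns(sample_meta, c("sample_id", group_field, "age"), "sample_meta")
  pb <- pseudobulk(expr, metadata, cluster, cluster_field = cluster_field)
  info <- sample_meta[match(rownames(pb$means), sample_meta$sample_id), ]
  groups <- .resolve_groups(info[[group_field]], groups)
  fits <- lapply(groups, function(g) {
    rows <- which(info[[group_field]] == g)
    if (length(rows) < min_samples) {
      stop(sprintf("cluster '%s': group '%s' has %d sample(s), need %d",
                   cluster, g, length(rows), min_samples), call. = FALSE)
    }
    fit_age_regression(pb$means[rows, , drop = FALSE], info$age[rows], group = g)
  })
  out <- aged_delta(fits[[1]], fits[[2]], groups = groups, alpha = alpha)
  cbind(cluster = cluster, out, stringsAsFactors = FALSE)
}

#' Select genes with large slope differences across clusters
#'
#' A gene is selected when its slope difference exceeds `delta_threshold`
#' (strictly) in at least `min_clusters` clusters. By default the absolute
#' difference `|delta|` is thresholded; set `use_abs = FALSE` to threshold
#' the signed value, the other reading of "difference over 0.5".
#'
#' @param delta_table data.frame with columns `gene`, `cluster`, `delta`
#'   (rows from [aged_cluster()] over several clusters).
#' @param delta_threshold strict threshold on the slope difference
#'   (default 0.5, log-normalized expression units per year).
#' @param min_clusters minimum number of qualifying clusters (default 3).
#' @param use_abs threshold `|delta|` (default) or signed `delta`.
#' @return list with `genes` (selected, ordered by number of qualifying
#'   clusters then mean |delta|), `counts` (qualifying-cluster count per
#'   gene), and `delta_wide` (genes x clusters matrix of delta for the
#'   selected genes, heat-map ready).
#' @export
select_aged_genes <- function(delta_table, delta_threshold = 0.5,
                              min_clusters = 3, use_abs = TRUE) {
  .assert_columns(delta_table, c("gene", "cluster", "delta"), "delta_table")
  clusters <- sort(unique(delta_table$cluster))
  if (length(clusters) < min_clusters) {
    warning(sprintf("only %d cluster(s) available but min_clusters = %d; returning an empty selection",
                    length(clusters), min_clusters), call. = FALSE)
    return(list(genes = character(0),
                counts = integer(0),
                delta_wide = matrix(numeric(0), 0, length(clusters),
                                    dimnames = list(NULL, clusters))))
  }
  val <- if (use_abs) abs(delta_table$delta) else delta_table$delta
  hit <- val > delta_threshold
  counts <- tapply(hit, delta_table$gene, sum)
  counts <- counts[counts >= min_clusters]
  if (!length(counts)) {
    return(list(genes = character(0), counts = integer(0),
                delta_wide = matrix(numeric(0), 0, length(clusters),
                                    dimnames = list(NULL, clusters))))
  }
  mean_abs <- tapply(abs(delta_table$delta), delta_table$gene, mean)[names(counts)]
  ord <- order(-as.integer(counts), -mean_abs, names(counts))
  genes <- names(counts)[ord]
  wide <- matrix(NA_real_, length(genes), length(clusters),
                 dimnames = list(genes, clusters))
  idx <- delta_table$gene %in% genes
  wide[cbind(match(delta_table$gene[idx], genes),
             match(delta_table$cluster[idx], clusters))] <- delta_table$delta[idx]
  list(genes = genes, counts = stats::setNames(as.integer(counts[ord]), genes),
       delta_wide = wide)
}

#' AGED analysis across clusters
#'
#' Runs [aged_cluster()] for every requested cluster (clusters without enough
#' samples per group are skipped with a warning), stacks the per-cluster
#' slope-difference tables and applies [select_aged_genes()].
#'
#' @inheritParams aged_cluster
#' @param clusters clusters to analyze; `NULL` means all in the metadata.
#' @inheritParams select_aged_genes
#' @return list with `deltas` (stacked table), `selection` (from
#'   [select_aged_genes()]), `skipped` (clusters skipped and why).
#' @export
aged_analysis <- function(expr, metadata, sample_meta, clusters = NULL,
                          cluster_field = "cluster",
                          group_field = "smoking_status", groups = NULL,
                          min_samples = 3, alpha = 0.05,
                          delta_threshold = 0.5, min_clusters = 3,
                          use_abs = TRUE) {
  clusters <- clusters %||% sort(unique(metadata[[cluster_field]]))
  tables <- list()
  skipped <- character(0)
  for (k in clusters) {
    res <- tryCatch(
      aged_cluster(expr, metadata, sample_meta, k,
                   cluster_field = cluster_field, group_field = group_field,
                   groups = groups, min_samples = min_samples, alpha = alpha),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping cluster '%s': %s", k, conditionMessage(res)),
              call. = FALSE)
      skipped <- c(skipped, k)
    } else {
      tables[[k]] <- res
    }
  }
  if (!length(tables)) stop("no cluster could be analyzed", call. = FALSE)
  deltas <- do.call(rbind, tables)
  rownames(deltas) <- NULL
  selection <- select_aged_genes(deltas, delta_threshold = delta_threshold,
                                 min_clusters = min_clusters, use_abs = use_abs)
  list(deltas = deltas, selection = selection, skipped = skipped)
}
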