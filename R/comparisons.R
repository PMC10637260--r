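#' Welch contrast of per-sample cell-type composition
#'
#' Computes, per sample, the fraction of its cells falling in each cluster
#' (fractions sum to 1 per sample; relative composition is used rather than
#' raw counts, which confound sequencing depth), then compares the two
#' exposure groups' fraction vectors per cluster with a Welch t test.
#' Clusters cannot be tested when either group has fewer than two samples;
#' they are flagged, not dropped.
#'
#' @param metadata per-cell data.frame with `cell_id`, `sample_id` and the
#'   cluster column.
#' @param sample_meta data.frame with `sample_id` and the group column.
#' @param cluster_field,group_field column names.
#' @param groups two group labels (contrast order); `NULL` uses the two
#'   present.
#' @return data.frame with per-cluster group mean fractions, Welch t, dof, p
#'   and the `tested` flag; the samples x clusters fraction matrix is
#'   attached as attribute `"fractions"`.
#' @export
cell_fraction_comparison <- function(metadata, sample_meta,
                                     cluster_field = "cluster",
                                     group_field = "smoking_status",
                                     groups = NULL) {
  .assert_columns(metadata, c("cell_id", "sample_id", cluster_field))
  .assert_columns(sample_meta, c("sample_id", group_field), "sample_meta")
  tab <- table(metadata$sample_id, metadata[[cluster_field]])
  fractions <- as.matrix(tab / rowSums(tab))
  grp <- sample_meta[[group_field]][match(rownames(fractions),
                                          sample_meta$sample_id)]
  groups <- .resolve_groups(grp[!is.na(grp)], groups)
  rows <- lapply(colnames(fractions), function(k) {
    x <- fractions[which(grp == groups[1]), k]
    y <- fractions[which(grp == groups[2]), k]
    if (length(x) >= 2 && length(y) >= 2) {
      wt <- welch_t_test(x, y)
      data.frame(cluster = k, mean_group1 = wt$means[1],
                 mean_group2 = wt$means[2], welch_t = wt$statistic,
                 dof = wt$dof, welch_p = wt$p_value,
                 n_group1 = length(x), n_group2 = length(y),
                 tested = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = k,
                 mean_group1 = if (length(x)) mean(x) else NA_real_,
                 mean_group2 = if (length(y)) mean(y) else NA_real_,
                 welch_t = NA_real_, dof = NA_real_, welch_p = NA_real_,
                 n_group1 = length(x), n_group2 = length(y),
                 tested = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("group1", groups[1], names(out))
  names(out) <- sub("group2", groups[2], names(out))
  rownames(out) <- NULL
  attr(out, "fractions") <- fractions
  out
}

#' Per-gene Welch contrast between groups within one cluster
#'
#' Compares the log-normalized expression of each requested gene between the
#' two exposure groups' cells of one cluster. Genes absent from the matrix
#' are omitted from the results and listed in `skipped`.
#'
#' @param expr log-normalized expression (genes x cells).
#' @param metadata per-cell data.frame with `cell_id`, the cluster and group
#'   columns.
#' @param cluster cluster label.
#' @param genes genes to test.
#' @param cluster_field,group_field metadata column names.
#' @param groups two group labels (contrast order); `NULL` uses the two
#'   present.
#' @return list with `results` (per-gene means, Welch t/dof/p) and `skipped`
#'   (absent genes).
#' @export
gene_group_comparison <- function(expr, metadata, cluster, genes,
                                  cluster_field = "cluster",
                                  group_field = "smoking_status",
                                  groups = NULL) {
  .assert_columns(metadata, c("cell_id", cluster_field, group_field))
  sub <- metadata[metadata[[cluster_field]] == cluster, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("cluster '%s' not found", cluster), call. = FALSE)
  groups <- .resolve_groups(sub[[group_field]], groups)
  skipped <- setdiff(genes, rownames(expr))
  genes <- intersect(genes, rownames(expr))
  cells1 <- intersect(sub$cell_id[sub[[group_field]] == groups[1]], colnames(expr))
  cells2 <- intersect(sub$cell_id[sub[[group_field]] == groups[2]], colnames(expr))
  rows <- lapply(genes, function(g) {
    x <- as.numeric(expr[g, cells1]); y <- as.numeric(expr[g, cells2])
    wt <- welch_t_test(x, y)
    data.frame(gene = g, mean_group1 = wt$means[1], mean_group2 = wt$means[2],
               welch_t = wt$statistic, dof = wt$dof, welch_p = wt$p_value,
               n_group1 = length(x), n_group2 = length(y),
               stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), mean_group1 = numeric(),
               mean_group2 = numeric(), welch_t = numeric(), dof = numeric(),
               welch_p = numeric(), n_group1 = integer(), n_group2 = integer())
  names(results) <- sub("group1", groups[1], names(results))
  names(results) <- sub("group2", groups[2], names(results))
  rownames(results) <- NULL
  list(results = results, skipped = skipped)
}
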