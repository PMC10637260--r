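#' Read gene sets from GMT or one-gene-per-line files
#'
#' A `.gmt` file contributes one set per line (name, description, genes,
#' tab-separated); any other file contributes a single set named after the
#' file (one gene per line). Empty sets are rejected.
#'
#' @param paths files, or a single directory whose files are all read.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  sets <- list()
  for (p in paths) {
    if (grepl("\\.gmt$", p, ignore.case = TRUE)) {
      for (line in readLines(p)) {
        fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3) {
          stop(sprintf("malformed GMT line in %s (need name, description, >=1 gene)", p),
               call. = FALSE)
        }
        sets[[fields[1]]] <- unique(fields[-(1:2)])
      }
    } else {
      genes <- unique(trimws(readLines(p)))
      genes <- genes[nzchar(genes)]
      if (!length(genes)) {
        stop(sprintf("gene-set file %s is empty", p), call. = FALSE)
      }
      sets[[tools::file_path_sans_ext(basename(p))]] <- genes
    }
  }
  if (!length(sets)) stop("no gene sets found", call. = FALSE)
  sets
}

.expression_bins <- function(avg, n_bins) {
  n <- length(avg)
  ord <- order(avg, seq_len(n))  # ties broken by stable gene order
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(n_bins), sizes)
  bin
}

#' Control-binned gene-set module score
#'
#' Re-implements the standard control-binned scoring of a gene set (the
#' `AddModuleScore` algorithm): genes are ranked by mean expression over all
#' cells and cut into `n_bins` near-equal bins; for each gene of the set,
#' `n_ctrl` control genes are sampled (seeded, without replacement) from the
#' gene's bin — a bin with at most `n_ctrl` genes is used in full — and the
#' per-cell score is the mean expression of the set genes minus the mean
#' expression of the pooled (deduplicated) control genes. Set genes missing
#' from the matrix are dropped with a message.
#'
#' @param expr log-normalized expression (genes x cells).
#' @param genes character vector of gene ids (the module).
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed for control sampling (the only randomness).
#' @param set_name label used in error messages.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, genes, n_bins = 24, n_ctrl = 100, seed = NULL,
                         set_name = "module") {
  if (n_bins < 1) stop("`n_bins` must be >= 1", call. = FALSE)
  all_genes <- rownames(expr)
  genes <- unique(genes)
  present <- intersect(genes, all_genes)
  if (!length(present)) {
    stop(sprintf("gene set '%s' has no genes in the matrix", set_name),
         call. = FALSE)
  }
  if (length(present) < length(genes)) {
    message(sprintf("gene set '%s': dropped %d gene(s) missing from the matrix",
                    set_name, length(genes) - length(present)))
  }
  avg <- .row_means(expr)
  bin <- .expression_bins(avg, min(n_bins, length(all_genes)))
  names(bin) <- all_genes
  draw_controls <- function() {
    unique(unlist(lapply(present, function(g) {
      pool <- all_genes[bin == bin[[g]]]
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    }), use.names = FALSE))
  }
  ctrl <- if (is.null(seed)) draw_controls() else
    withr::with_seed(seed, draw_controls())
  score <- .col_means(expr[present, , drop = FALSE]) -
    .col_means(expr[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(expr))
}

#' Per-cluster group contrast of module scores
#'
#' For each cluster, compares the per-cell module scores of the two exposure
#' groups with a Welch t test and reports the per-group medians (the
#' heat-map quantity). Clusters missing a group, or with fewer than two
#' scored cells in a group, are flagged `tested = FALSE` rather than dropped.
#'
#' @param scores named per-cell score vector from [module_score()].
#' @param metadata per-cell data.frame with `cell_id`, the cluster column and
#'   the group column.
#' @param cluster_field,group_field metadata column names.
#' @param groups two group labels (contrast order); `NULL` uses the two
#'   present.
#' @return data.frame with per-cluster medians, Welch t, dof, p, group sizes
#'   and the `tested` flag.
#' @export
compare_module_scores <- function(scores, metadata, cluster_field = "cluster",
                                  group_field = "smoking_status",
                                  groups = NULL) {
  .assert_columns(metadata, c("cell_id", cluster_field, group_field))
  metadata <- metadata[metadata$cell_id %in% names(scores), , drop = FALSE]
  groups <- .resolve_groups(metadata[[group_field]], groups)
  clusters <- sort(unique(metadata[[cluster_field]]))
  rows <- lapply(clusters, function(k) {
    sub <- metadata[metadata[[cluster_field]] == k, , drop = FALSE]
    s1 <- scores[sub$cell_id[sub[[group_field]] == groups[1]]]
    s2 <- scores[sub$cell_id[sub[[group_field]] == groups[2]]]
    if (length(s1) >= 2 && length(s2) >= 2) {
      wt <- welch_t_test(s1, s2)
      data.frame(cluster = k, median_group1 = wt$medians[1],
                 median_group2 = wt$medians[2], welch_t = wt$statistic,
                 dof = wt$dof, welch_p = wt$p_value,
                 n_group1 = length(s1), n_group2 = length(s2),
                 tested = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = k,
                 median_group1 = if (length(s1)) stats::median(s1) else NA_real_,
                 median_group2 = if (length(s2)) stats::median(s2) else NA_real_,
                 welch_t = NA_real_, dof = NA_real_, welch_p = NA_real_,
                 n_group1 = length(s1), n_group2 = length(s2),
                 tested = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("group1", groups[1], names(out))
  names(out) <- sub("group2", groups[2], names(out))
  rownames(out) <- NULL
  out
}
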