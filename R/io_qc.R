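#' Sparse count-matrix container
#'
#' Light container for a genes x cells matrix of raw UMI counts with unique
#' gene and cell identifiers and a mitochondrial-gene mask.
#'
#' @param counts sparse (or dense) genes x cells matrix of non-negative
#'   integer counts with row and column names.
#' @param mito_mask logical vector flagging mitochondrial genes, one entry per
#'   gene. When `NULL`, genes whose name starts with `mito_prefix` are flagged.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return An object of class `sc_counts` with elements `counts`
#'   (`dgCMatrix`), `gene_ids`, `cell_ids`, `mito_mask`.
#' @export
sc_counts <- function(counts, mito_mask = NULL, mito_prefix = "MT-") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("counts must carry gene (row) and cell (column) names", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(mito_mask)) {
    mito_mask <- startsWith(gene_ids, mito_prefix)
  }
  if (length(mito_mask) != nrow(counts)) {
    stop("mito_mask length must equal the number of genes", call. = FALSE)
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 mito_mask = as.logical(mito_mask)),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells (%d mitochondrial genes, %.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_mask),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Read a CellRanger-style MatrixMarket triplet
#'
#' Reads `matrix.mtx` (genes in rows, cells in columns), a features TSV (gene
#' id and optionally a symbol column) and a barcodes file (one cell id per
#' line), validating that the declared dimensions agree.
#'
#' @param matrix_path path to the MatrixMarket coordinate file.
#' @param features_path path to the features TSV.
#' @param barcodes_path path to the barcodes file.
#' @param mito_prefix gene-symbol prefix flagging mitochondrial genes.
#' @return An [sc_counts] object.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        mito_prefix = "MT-") {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop(sprintf("malformed MatrixMarket file %s: %s",
                                                 matrix_path, conditionMessage(e)),
                                         call. = FALSE))
  features <- utils::read.delim(features_path, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- readLines(barcodes_path)
  if (nrow(features) != nrow(m)) {
    stop(sprintf("features file %s has %d rows but %s declares %d gene rows",
                 features_path, nrow(features), matrix_path, nrow(m)),
         call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop(sprintf("barcodes file %s has %d lines but %s declares %d cell columns",
                 barcodes_path, length(barcodes), matrix_path, ncol(m)),
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop(sprintf("duplicate cell barcodes in %s", barcodes_path), call. = FALSE)
  }
  if (anyDuplicated(features[[1]])) {
    stop(sprintf("duplicate gene ids in %s", features_path), call. = FALSE)
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes
  sc_counts(m, mito_mask = startsWith(symbols, mito_prefix))
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell, the number of detected genes (`n_features`, genes with
#' a nonzero count), the total UMI count, and the percentage of counts mapping
#' to mitochondrial genes. A cell with zero total counts gets
#' `percent_mt = 0` by convention so it can still be removed downstream by the
#' feature filter.
#'
#' @param x an [sc_counts] object.
#' @return data.frame with columns `cell_id`, `n_features`, `total_counts`,
#'   `percent_mt`.
#' @export
compute_qc <- function(x) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  n_features <- Matrix::colSums(m > 0)
  total_counts <- Matrix::colSums(m)
  mito_counts <- if (any(x$mito_mask)) {
    Matrix::colSums(m[x$mito_mask, , drop = FALSE])
  } else {
    numeric(ncol(m))
  }
  percent_mt <- ifelse(total_counts > 0, 100 * mito_counts / total_counts, 0)
  data.frame(cell_id = x$cell_ids,
             n_features = as.integer(n_features),
             total_counts = as.numeric(total_counts),
             percent_mt = as.numeric(percent_mt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' Keeps exactly the cells with `n_features > min_features` and
#' `percent_mt < max_mito`. Both inequalities are strict, so cells sitting
#' exactly on either threshold are removed. Cell order is preserved.
#'
#' @param x an [sc_counts] object.
#' @param qc QC table from [compute_qc()]; recomputed when `NULL`.
#' @param min_features minimum detected-gene count (strict, default 1000).
#' @param max_mito maximum mitochondrial percentage (strict, default 20).
#' @return A filtered [sc_counts] object.
#' @export
filter_cells <- function(x, qc = NULL, min_features = 1000, max_mito = 20) {
  stopifnot(inherits(x, "sc_counts"))
  if (min_features < 0 || max_mito < 0) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  if (is.null(qc)) qc <- compute_qc(x)
  if (!identical(qc$cell_id, x$cell_ids)) {
    stop("qc table does not match the cells of `x`; recompute with compute_qc()",
         call. = FALSE)
  }
  keep <- qc$n_features > min_features & qc$percent_mt < max_mito
  if (!any(keep)) {
    stop(sprintf("no cells pass the QC thresholds (n_features > %s, percent_mt < %s)",
                 min_features, max_mito), call. = FALSE)
  }
  sc_counts(x$counts[, keep, drop = FALSE], mito_mask = x$mito_mask)
}

#' Log-normalize counts (log1p of counts per 10,000)
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`. A zero
#' raw count maps to exactly 0, so the sparsity pattern is preserved. Cells
#' with zero total counts are rejected; remove them with [filter_cells()]
#' first.
#'
#' @param x an [sc_counts] object.
#' @param scale_factor library-size target (default 10,000).
#' @return A `dgCMatrix` (genes x cells) of log-normalized expression.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop(sprintf("%d cell(s) have zero total counts; run filter_cells() first",
                 sum(totals == 0)), call. = FALSE)
  }
  per_entry <- rep.int(scale_factor / totals, diff(m@p))
  m@x <- log1p(m@x * per_entry)
  m
}
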