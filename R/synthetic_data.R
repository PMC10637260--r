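#' Configuration for the synthetic atlas generator
#'
#' Describes a multi-sample, multi-cluster UMI-count atlas with two exposure
#' groups. Counts are negative binomial around cluster-specific mean programs;
#' within-cluster expression heterogeneity is controlled per cluster and group
#' by the standard deviation of a per-cell lognormal scaling factor applied to
#' the cluster's program genes (larger SD lowers pairwise cell-cell
#' correlation); selected "aged" genes have log-normalized mean expression
#' that is linear in donor age with group-specific slopes.
#'
#' Gene identifiers are deterministic: the first `mito_gene_count` genes are
#' named `MT-01`, `MT-02`, ... and the remainder `GENE0001`, `GENE0002`, ...,
#' so planted aged genes can be named ahead of generation.
#'
#' @param n_samples_per_group samples (donors) per exposure group.
#' @param n_clusters number of cell clusters.
#' @param cells_per_sample_per_cluster cells contributed by each sample to
#'   each cluster.
#' @param n_genes total number of genes, including mitochondrial genes.
#' @param mito_gene_count number of mitochondrial genes (flagged by the
#'   `MT-` prefix).
#' @param age_range two-element numeric, donor ages are drawn uniformly (in
#'   whole years) within this range.
#' @param age_offset_group1 additive shift (years) applied to the first
#'   group's ages, to mimic cohort age imbalance; default 0.
#' @param nb_mean_baseline baseline negative-binomial mean per gene.
#' @param nb_dispersion negative-binomial size (dispersion) parameter; the
#'   count variance is `mu + mu^2 / nb_dispersion`.
#' @param heterogeneity_sd per cluster x group SD of the lognormal program
#'   scaling factor. A scalar is recycled; otherwise a matrix with
#'   `n_clusters` rows and one column per group (in `groups` order).
#' @param program_fraction fraction of (non-mitochondrial) genes forming each
#'   cluster's expression program.
#' @param program_strength fold elevation of program-gene means.
#' @param mito_strength fold elevation of mitochondrial-gene means (high
#'   mitochondrial load is typical of real cells).
#' @param low_quality_fraction fraction of cells generated as low-quality
#'   (shallow, mitochondria-rich); these are what QC is expected to remove.
#' @param low_quality_depth library-depth factor applied to low-quality cells.
#' @param low_quality_mito extra mitochondrial fold applied to low-quality
#'   cells.
#' @param aged_genes list of planted age effects; each element is a list with
#'   fields `gene` (a gene id), `clusters` (character vector of cluster
#'   labels), `slope_group1` and `slope_group2` (log-normalized expression
#'   units per year for the two groups in `groups` order), and optionally
#'   `baseline`, the log-normalized level at the mid-age (defaults to the
#'   gene's cluster baseline level).
#' @param groups two exposure-group labels; the first is the "exposed" group.
#' @param seed integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_group = 10,
                       n_clusters = 5,
                       cells_per_sample_per_cluster = 30,
                       n_genes = 2000,
                       mito_gene_count = 13,
                       age_range = c(40, 80),
                       age_offset_group1 = 0,
                       nb_mean_baseline = 1,
                       nb_dispersion = 2,
                       heterogeneity_sd = 0.3,
                       program_fraction = 0.25,
                       program_strength = 4,
                       mito_strength = 15,
                       low_quality_fraction = 0.05,
                       low_quality_depth = 0.3,
                       low_quality_mito = 4,
                       aged_genes = list(),
                       groups = c("smoker", "never"),
                       seed = 1L) {
  for (nm in c("n_samples_per_group", "n_clusters",
               "cells_per_sample_per_cluster", "n_genes")) {
    if (!.is_count(get(nm))) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (!is.numeric(mito_gene_count) || mito_gene_count < 0 ||
      mito_gene_count != round(mito_gene_count) || mito_gene_count >= n_genes) {
    stop("`mito_gene_count` must be a non-negative integer < n_genes", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("`age_range` must be (lo, hi) with lo < hi", call. = FALSE)
  }
  if (nb_mean_baseline <= 0) stop("`nb_mean_baseline` must be positive", call. = FALSE)
  if (nb_dispersion <= 0) stop("`nb_dispersion` must be positive", call. = FALSE)
  if (program_fraction < 0 || program_fraction >= 1) {
    stop("`program_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (length(groups) != 2 || anyDuplicated(groups)) {
    stop("`groups` must be two distinct labels", call. = FALSE)
  }
  cluster_labels <- paste0("cluster", seq_len(n_clusters))
  het <- heterogeneity_sd
  if (is.null(dim(het))) {
    if (length(het) == 1) {
      het <- matrix(het, n_clusters, 2)
    } else if (length(het) == 2) {
      het <- matrix(rep(het, each = n_clusters), n_clusters, 2)
    } else {
      stop("`heterogeneity_sd` must be a scalar, length-2 vector, or n_clusters x 2 matrix",
           call. = FALSE)
    }
  }
  het <- as.matrix(het)
  if (!all(dim(het) == c(n_clusters, 2))) {
    stop("`heterogeneity_sd` matrix must be n_clusters x 2", call. = FALSE)
  }
  if (any(het < 0)) stop("`heterogeneity_sd` must be non-negative", call. = FALSE)
  dimnames(het) <- list(cluster_labels, groups)

  gene_ids <- c(sprintf("MT-%02d", seq_len(mito_gene_count)),
                sprintf("GENE%04d", seq_len(n_genes - mito_gene_count)))
  for (a in aged_genes) {
    if (!all(c("gene", "clusters", "slope_group1", "slope_group2") %in% names(a))) {
      stop("each aged_genes entry needs fields gene, clusters, slope_group1, slope_group2",
           call. = FALSE)
    }
    if (!a$gene %in% gene_ids) {
      stop(sprintf("aged gene '%s' is not among the generated gene ids", a$gene),
           call. = FALSE)
    }
    if (startsWith(a$gene, "MT-")) {
      stop("aged effects cannot be planted on mitochondrial genes", call. = FALSE)
    }
    bad <- setdiff(a$clusters, cluster_labels)
    if (length(bad)) {
      stop(sprintf("aged gene '%s' references unknown cluster(s): %s",
                   a$gene, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_clusters = as.integer(n_clusters),
    cells_per_sample_per_cluster = as.integer(cells_per_sample_per_cluster),
    n_genes = as.integer(n_genes),
    mito_gene_count = as.integer(mito_gene_count),
    age_range = as.numeric(age_range),
    age_offset_group1 = as.numeric(age_offset_group1),
    nb_mean_baseline = as.numeric(nb_mean_baseline),
    nb_dispersion = as.numeric(nb_dispersion),
    heterogeneity_sd = het,
    program_fraction = as.numeric(program_fraction),
    program_strength = as.numeric(program_strength),
    mito_strength = as.numeric(mito_strength),
    low_quality_fraction = as.numeric(low_quality_fraction),
    low_quality_depth = as.numeric(low_quality_depth),
    low_quality_mito = as.numeric(low_quality_mito),
    aged_genes = aged_genes,
    groups = as.character(groups),
    cluster_labels = cluster_labels,
    gene_ids = gene_ids,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic atlas
#'
#' Draws the atlas described by a [sim_config()]: negative-binomial counts
#' around cluster programs with per-cell lognormal heterogeneity (the
#' lognormal is parameterized to have mean 1, so heterogeneity changes
#' cell-cell correlation without changing mean expression), uniform donor
#' ages, planted low-quality cells, and planted age-linear genes. The
#' `ground_truth` element records every planted effect:
#'
#' * `centrality_direction`: per cluster, the expected sign of the
#'   group1 - group2 difference in median closeness centrality implied by the
#'   heterogeneity SDs (more heterogeneity means lower centrality);
#' * `true_slopes` / `true_delta`: planted per-group slopes and their
#'   difference, in log-normalized expression units per year;
#' * `aged_baseline`: the planted log-normalized mean at the mid-age;
#' * `program_genes`, `low_quality_cells`.
#'
#' Identical configurations (including the seed) yield identical atlases.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sc_atlas`: list with `counts` ([sc_counts]),
#'   `cell_meta` (cell_id, sample_id, cluster), `sample_meta` (sample_id,
#'   group column `smoking_status`, age, gender), `ground_truth`, `config`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .generate_atlas_impl(config))
}

# Expected log-normalized value of an NB(c, theta) count, with the cell total
# approximated by its expectation T0 + c.
.expected_lognorm <- function(c, T0, theta, scale = 1e4) {
  if (c <= 0) return(0)
  s <- scale / (T0 + c)
  hi <- stats::qnbinom(1 - 1e-12, size = theta, mu = c)
  x <- 0:max(hi, 1)
  sum(stats::dnbinom(x, size = theta, mu = c) * log1p(x * s))
}

# Invert .expected_lognorm for the NB mean achieving target t (monotone in c).
.invert_lognorm_mean <- function(t, T0, theta, scale = 1e4) {
  if (t <= 0) return(0)
  stats::uniroot(function(c) .expected_lognorm(c, T0, theta, scale) - t,
                 lower = 1e-9, upper = max(10, T0), extendInt = "upX",
                 tol = 1e-10)$root
}

.generate_atlas_impl <- function(cfg) {
  G <- cfg$n_genes
  gene_ids <- cfg$gene_ids
  mito_mask <- startsWith(gene_ids, "MT-")
  clusters <- cfg$cluster_labels
  groups <- cfg$groups
  n_samples <- 2L * cfg$n_samples_per_group

  ## --- samples -------------------------------------------------------------
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  sample_group <- rep(groups, each = cfg$n_samples_per_group)
  ages <- round(stats::runif(n_samples, cfg$age_range[1], cfg$age_range[2]))
  ages[sample_group == groups[1]] <- ages[sample_group == groups[1]] +
    cfg$age_offset_group1
  gender <- sample(c("male", "female"), n_samples, replace = TRUE)
  sample_meta <- data.frame(sample_id = sample_ids,
                            smoking_status = sample_group,
                            age = as.numeric(ages),
                            gender = gender,
                            stringsAsFactors = FALSE)

  ## --- cluster mean programs ----------------------------------------------
  base_mean <- rep(cfg$nb_mean_baseline, G)
  base_mean[mito_mask] <- base_mean[mito_mask] * cfg$mito_strength
  aged_ids <- vapply(cfg$aged_genes, `[[`, "", "gene")
  eligible <- which(!mito_mask & !(gene_ids %in% aged_ids))
  n_prog <- round(cfg$program_fraction * G)
  M <- matrix(base_mean, G, cfg$n_clusters,
              dimnames = list(gene_ids, clusters))
  program_genes <- stats::setNames(vector("list", cfg$n_clusters), clusters)
  for (k in seq_len(cfg$n_clusters)) {
    pk <- if (n_prog > 0) sort(sample(eligible, min(n_prog, length(eligible)))) else integer(0)
    program_genes[[k]] <- gene_ids[pk]
    M[pk, k] <- M[pk, k] * cfg$program_strength
  }
  totals0 <- colSums(M)  # expected per-cell totals per cluster

  ## --- planted age-linear genes -------------------------------------------
  ## The planted quantity is the per-cell MEAN of log-normalized expression
  ## (that is what pseudobulk estimates), so the NB mean count c for a target
  ## t solves E[log1p(X * 1e4 / (T0 + c))] = t with X ~ NB(c, theta). log1p
  ## is concave, so the naive inverse log1p(c * 1e4 / (T0 + c)) = t would
  ## understate t at noisy low counts and distort the planted slopes.
  age_mid <- mean(cfg$age_range)
  true_slopes <- list()
  aged_baseline <- list()
  aged_mu <- list()  # aged_mu[[cluster]][gene_id, sample_id]
  for (a in cfg$aged_genes) {
    g <- a$gene
    slopes <- stats::setNames(c(a$slope_group1, a$slope_group2), groups)
    for (k in a$clusters) {
      t0 <- a$baseline %||% log1p(1e4 * M[g, k] / totals0[k])
      tvals <- t0 + slopes[sample_group] * (ages - age_mid)
      if (any(tvals < 0) || any(tvals > 8.5)) {
        stop(sprintf(
          "planted slope for gene '%s' in %s leaves the representable log-normalized range (targets must stay in [0, 8.5]); shrink the slope or the age range",
          g, k), call. = FALSE)
      }
      T0 <- totals0[k] - M[g, k]
      mu <- vapply(tvals, .invert_lognorm_mean, 0,
                   T0 = T0, theta = cfg$nb_dispersion)
      if (is.null(aged_mu[[k]])) {
        aged_mu[[k]] <- matrix(NA_real_, 0, n_samples,
                               dimnames = list(NULL, sample_ids))
      }
      aged_mu[[k]] <- rbind(aged_mu[[k]],
                            matrix(mu, 1, n_samples,
                                   dimnames = list(g, sample_ids)))
      true_slopes[[length(true_slopes) + 1L]] <-
        data.frame(gene = g, cluster = k,
                   group = groups, slope = unname(slopes),
                   stringsAsFactors = FALSE)
      aged_baseline[[length(aged_baseline) + 1L]] <-
        data.frame(gene = g, cluster = k, baseline = unname(t0),
                   age_mid = age_mid, stringsAsFactors = FALSE)
    }
  }
  true_slopes <- if (length(true_slopes)) do.call(rbind, true_slopes) else
    data.frame(gene = character(), cluster = character(),
               group = character(), slope = numeric())
  aged_baseline <- if (length(aged_baseline)) do.call(rbind, aged_baseline) else
    data.frame(gene = character(), cluster = character(),
               baseline = numeric(), age_mid = numeric())
  if (nrow(true_slopes)) {
    sw <- true_slopes[true_slopes$group == groups[1], ]
    nv <- true_slopes[true_slopes$group == groups[2], ]
    key <- paste(sw$gene, sw$cluster)
    nv <- nv[match(key, paste(nv$gene, nv$cluster)), ]
    true_delta <- data.frame(gene = sw$gene, cluster = sw$cluster,
                             delta = sw$slope - nv$slope,
                             stringsAsFactors = FALSE)
  } else {
    true_delta <- data.frame(gene = character(), cluster = character(),
                             delta = numeric())
  }

  ## --- cells ---------------------------------------------------------------
  blocks <- vector("list", n_samples * cfg$n_clusters)
  meta <- vector("list", n_samples * cfg$n_clusters)
  lq_cells <- character(0)
  bi <- 0L
  nc <- cfg$cells_per_sample_per_cluster
  for (s in seq_len(n_samples)) {
    for (k in seq_len(cfg$n_clusters)) {
      bi <- bi + 1L
      kl <- clusters[k]
      cell_ids <- sprintf("%s_%s_c%03d", sample_ids[s], kl, seq_len(nc))
      mu <- matrix(M[, k], G, nc, dimnames = list(gene_ids, cell_ids))
      ## per-cell lognormal program scaling (mean-1 parameterization)
      sd_k <- cfg$heterogeneity_sd[kl, sample_group[s]]
      if (sd_k > 0 && length(program_genes[[k]])) {
        f <- stats::rlnorm(nc, meanlog = -sd_k^2 / 2, sdlog = sd_k)
        pg <- program_genes[[k]]
        mu[pg, ] <- mu[pg, , drop = FALSE] *
          matrix(f, length(pg), nc, byrow = TRUE)
      }
      ## planted aged genes override the program mean for this sample
      if (!is.null(aged_mu[[kl]])) {
        for (g in rownames(aged_mu[[kl]])) {
          mu[g, ] <- aged_mu[[kl]][g, sample_ids[s]]
        }
      }
      ## low-quality cells: shallow and mitochondria-rich
      lq <- stats::runif(nc) < cfg$low_quality_fraction
      if (any(lq)) {
        mu[, lq] <- mu[, lq, drop = FALSE] * cfg$low_quality_depth
        mu[mito_mask, lq] <- mu[mito_mask, lq, drop = FALSE] * cfg$low_quality_mito
        lq_cells <- c(lq_cells, cell_ids[lq])
      }
      cnt <- matrix(stats::rnbinom(G * nc, size = cfg$nb_dispersion, mu = mu),
                    G, nc, dimnames = dimnames(mu))
      blocks[[bi]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
      meta[[bi]] <- data.frame(cell_id = cell_ids,
                               sample_id = sample_ids[s],
                               cluster = kl,
                               stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  cell_meta <- do.call(rbind, meta)
  rownames(cell_meta) <- NULL

  direction <- sign(cfg$heterogeneity_sd[, groups[2]] -
                    cfg$heterogeneity_sd[, groups[1]])
  ground_truth <- list(
    centrality_direction = stats::setNames(as.numeric(direction), clusters),
    true_slopes = true_slopes,
    true_delta = true_delta,
    aged_baseline = aged_baseline,
    program_genes = program_genes,
    low_quality_cells = lq_cells
  )
  structure(list(counts = sc_counts(counts, mito_mask = mito_mask),
                 cell_meta = cell_meta,
                 sample_meta = sample_meta,
                 ground_truth = ground_truth,
                 config = cfg),
            class = "sc_atlas")
}

#' @export
print.sc_atlas <- function(x, ...) {
  cat(sprintf("<sc_atlas> %d genes x %d cells, %d samples, %d clusters, groups: %s\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              nrow(x$sample_meta), length(x$config$cluster_labels),
              paste(x$config$groups, collapse = " vs ")))
  invisible(x)
}

#' Cell metadata joined with sample metadata
#'
#' @param atlas an `sc_atlas` object.
#' @return data.frame with one row per cell: cell_id, sample_id, cluster,
#'   smoking_status, age, gender.
#' @export
cell_metadata <- function(atlas) {
  stopifnot(inherits(atlas, "sc_atlas"))
  merge(atlas$cell_meta, atlas$sample_meta, by = "sample_id", sort = FALSE)[
    , c("cell_id", "sample_id", "cluster", "smoking_status", "age", "gender")]
}

#' Write an atlas as a MatrixMarket triplet plus metadata
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `cell_metadata.tsv`
#' (joined with sample age/group/gender), `sample_metadata.tsv` and
#' `ground_truth.json` into `out_dir`. The files round-trip through
#' [read_atlas()] / [read_counts()].
#'
#' @param atlas an `sc_atlas` object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_atlas <- function(atlas, out_dir) {
  stopifnot(inherits(atlas, "sc_atlas"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  paths <- file.path(out_dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                                "cell_metadata.tsv", "sample_metadata.tsv",
                                "ground_truth.json"))
  names(paths) <- c("matrix", "features", "barcodes", "cell_meta",
                    "sample_meta", "ground_truth")
  m <- atlas$counts$counts
  Matrix::writeMM(m, paths[["matrix"]])
  utils::write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                     paths[["features"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), paths[["barcodes"]])
  utils::write.table(cell_metadata(atlas), paths[["cell_meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$sample_meta, paths[["sample_meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(atlas$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an atlas directory written by [write_atlas()]
#'
#' @param dir directory holding the MTX triplet and metadata TSVs.
#' @param mito_prefix mitochondrial gene-symbol prefix.
#' @return list with `counts` ([sc_counts]), `cell_meta`, `sample_meta`, and
#'   `ground_truth` (NULL when absent).
#' @export
read_atlas <- function(dir, mito_prefix = "MT-") {
  counts <- read_counts(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"),
                        mito_prefix = mito_prefix)
  cell_meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                                 stringsAsFactors = FALSE)
  sample_meta <- utils::read.delim(file.path(dir, "sample_metadata.tsv"),
                                   stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
  list(counts = counts, cell_meta = cell_meta, sample_meta = sample_meta,
       ground_truth = ground_truth)
}
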