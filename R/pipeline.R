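#' Pipeline configuration
#'
#' Collects every tunable of the pipeline stages with defaults matching the
#' analysis conventions used throughout the package: QC thresholds
#' `min_features = 1000` and `max_mito = 20` (both strict), VARIED subsample
#' size and sufficiency threshold of 100 cells, slope-difference selection at
#' `delta_threshold = 0.5` in at least `min_clusters = 3` clusters, and a
#' significance cut of 0.05. The default synthetic atlas has 10 samples per
#' group, 5 clusters and 2,000 genes, with one cluster given elevated
#' exposed-group heterogeneity and two genes carrying group-specific age
#' slopes, so every stage has signal to find.
#'
#' @param sim a [sim_config()] describing the synthetic atlas; ignored when
#'   `input_dir` is given.
#' @param input_dir optional directory with a written atlas ([read_atlas()])
#'   to analyze instead of simulating.
#' @param seed master seed; per-stage seeds are small fixed offsets from it.
#' @param min_features,max_mito QC filter thresholds.
#' @param subsample_size,n_reps,min_cells VARIED parameters.
#' @param run_convergence also profile VARIED convergence (slower; default
#'   FALSE).
#' @param convergence_sizes subsample sizes for the convergence profile.
#' @param delta_threshold,min_clusters,use_abs AGED selection parameters.
#' @param min_samples minimum samples per group for an age regression.
#' @param alpha significance threshold.
#' @param module_sets named list of gene-id vectors, or a path readable by
#'   [read_gene_sets()]; `NULL` scores three seeded random 30-gene sets
#'   (synthetic modules, useful for exercising the stage).
#' @param n_bins,n_ctrl module-score parameters.
#' @param contrast_genes genes for the per-gene group contrast; `NULL` picks
#'   the planted aged genes (if any) plus the first two others.
#' @param contrast_cluster cluster for the per-gene contrast; `NULL` uses the
#'   top-ranked VARIED cluster.
#' @param groups the two exposure-group labels (contrast order).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, seed = 1L,
                            min_features = 1000, max_mito = 20,
                            subsample_size = 100, n_reps = 20, min_cells = 100,
                            run_convergence = FALSE,
                            convergence_sizes = c(25, 50, 100),
                            delta_threshold = 0.5, min_clusters = 3,
                            use_abs = TRUE, min_samples = 3, alpha = 0.05,
                            module_sets = NULL, n_bins = 24, n_ctrl = 100,
                            contrast_genes = NULL, contrast_cluster = NULL,
                            groups = c("smoker", "never")) {
  if (is.null(sim) && is.null(input_dir)) {
    het <- matrix(0.3, 5, 2)
    het[1, ] <- c(0.7, 0.2)  # cluster1: elevated exposed-group heterogeneity
    sim <- sim_config(
      heterogeneity_sd = het,
      aged_genes = list(
        list(gene = "GENE0101", clusters = paste0("cluster", 1:4),
             slope_group1 = 0.030, slope_group2 = -0.010),
        list(gene = "GENE0202", clusters = paste0("cluster", 2:5),
             slope_group1 = -0.020, slope_group2 = 0.015)),
      groups = groups,
      seed = seed)
  }
  structure(list(sim = sim, input_dir = input_dir, seed = as.integer(seed),
                 min_features = min_features, max_mito = max_mito,
                 subsample_size = subsample_size, n_reps = n_reps,
                 min_cells = min_cells, run_convergence = run_convergence,
                 convergence_sizes = convergence_sizes,
                 delta_threshold = delta_threshold,
                 min_clusters = min_clusters, use_abs = use_abs,
                 min_samples = min_samples, alpha = alpha,
                 module_sets = module_sets, n_bins = n_bins, n_ctrl = n_ctrl,
                 contrast_genes = contrast_genes,
                 contrast_cluster = contrast_cluster,
                 groups = as.character(groups)),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[scmeta] stage %-12s %6.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> QC -> normalize -> VARIED -> AGED ->
#' module scores -> composition and gene contrasts, writing all result
#' tables as TSVs plus a JSON run manifest into `out_dir`. Given the same
#' configuration the output bundle is byte-identical across runs (the
#' manifest deliberately records no timestamps).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and `files`
#'   (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  files <- character(0)
  groups <- config$groups

  ## --- input ---------------------------------------------------------------
  if (!is.null(config$input_dir)) {
    atlas_in <- .stage("load", read_atlas(config$input_dir))
    counts <- atlas_in$counts
    cell_meta <- atlas_in$cell_meta
    sample_meta <- atlas_in$sample_meta
    ground_truth <- atlas_in$ground_truth
  } else {
    atlas <- .stage("simulate", generate_atlas(config$sim))
    counts <- atlas$counts
    cell_meta <- cell_metadata(atlas)
    sample_meta <- atlas$sample_meta
    ground_truth <- atlas$ground_truth
  }
  n_simulated <- ncol(counts$counts)

  ## --- QC + normalization --------------------------------------------------
  qc <- .stage("qc", compute_qc(counts))
  filtered <- filter_cells(counts, qc, min_features = config$min_features,
                           max_mito = config$max_mito)
  qc$kept <- qc$cell_id %in% filtered$cell_ids
  files <- c(files, .write_tsv(qc, file.path(out_dir, "qc_report.tsv")))
  expr <- .stage("normalize", normalize_counts(filtered))
  meta <- cell_meta[cell_meta$cell_id %in% colnames(expr), , drop = FALSE]

  ## --- VARIED --------------------------------------------------------------
  va <- .stage("varied", varied_analysis(
    expr, meta, groups = groups, subsample_size = config$subsample_size,
    n_reps = config$n_reps, min_cells = config$min_cells,
    seed = config$seed + 11L))
  files <- c(files, .write_tsv(va$table, file.path(out_dir, "varied_results.tsv")))
  centr <- do.call(rbind, lapply(va$results, function(r) {
    data.frame(cluster = r$cluster,
               group = rep(r$groups, lengths(r$centrality)),
               centrality = unlist(r$centrality, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(centr) <- NULL
  files <- c(files, .write_tsv(centr, file.path(out_dir, "centralities.tsv")))
  if (isTRUE(config$run_convergence)) {
    top <- va$table$cluster[1]
    conv <- .stage("convergence", varied_convergence(
      expr, meta, top, groups = groups, sizes = config$convergence_sizes,
      n_reps = config$n_reps, seed = config$seed + 13L))
    files <- c(files, .write_tsv(conv, file.path(out_dir, "convergence.tsv")))
  }

  ## --- AGED ----------------------------------------------------------------
  aged <- .stage("aged", aged_analysis(
    expr, meta, sample_meta, groups = groups,
    min_samples = config$min_samples, alpha = config$alpha,
    delta_threshold = config$delta_threshold,
    min_clusters = config$min_clusters, use_abs = config$use_abs))
  files <- c(files, .write_tsv(aged$deltas, file.path(out_dir, "aged_deltas.tsv")))
  sel <- data.frame(gene = aged$selection$genes,
                    n_clusters_over_threshold = as.integer(aged$selection$counts),
                    stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(sel, file.path(out_dir, "aged_selected_genes.tsv")))
  wide <- data.frame(gene = rownames(aged$selection$delta_wide),
                     aged$selection$delta_wide, check.names = FALSE,
                     stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(wide, file.path(out_dir, "aged_delta_wide.tsv")))

  ## --- module scores -------------------------------------------------------
  sets <- config$module_sets
  if (is.character(sets)) sets <- read_gene_sets(sets)
  if (is.null(sets)) {
    sets <- withr::with_seed(config$seed + 17L, {
      lapply(stats::setNames(1:3, paste0("synthetic_module_", 1:3)),
             function(i) sample(rownames(expr), 30))
    })
  }
  mod <- .stage("modulescore", {
    lapply(stats::setNames(names(sets), names(sets)), function(nm) {
      sc <- module_score(expr, sets[[nm]], n_bins = config$n_bins,
                         n_ctrl = config$n_ctrl, seed = config$seed + 19L,
                         set_name = nm)
      list(scores = sc,
           summary = compare_module_scores(sc, meta, groups = groups))
    })
  })
  score_tab <- do.call(rbind, lapply(names(mod), function(nm) {
    data.frame(cell_id = names(mod[[nm]]$scores), set = nm,
               score = unname(mod[[nm]]$scores), stringsAsFactors = FALSE)
  }))
  files <- c(files, .write_tsv(score_tab, file.path(out_dir, "module_scores.tsv")))
  mod_summary <- do.call(rbind, lapply(names(mod), function(nm) {
    cbind(set = nm, mod[[nm]]$summary, stringsAsFactors = FALSE)
  }))
  rownames(mod_summary) <- NULL
  files <- c(files, .write_tsv(mod_summary, file.path(out_dir, "module_summary.tsv")))

  ## --- composition + gene contrasts ---------------------------------------
  comp <- .stage("composition", cell_fraction_comparison(
    meta, sample_meta, groups = groups))
  files <- c(files, .write_tsv(comp, file.path(out_dir, "cell_fractions.tsv")))
  contrast_cluster <- config$contrast_cluster %||% va$table$cluster[1]
  contrast_genes <- config$contrast_genes
  if (is.null(contrast_genes)) {
    planted <- unique(if (!is.null(ground_truth)) {
      vapply(ground_truth$true_delta$gene, as.character, "")
    } else character(0))
    contrast_genes <- utils::head(unique(c(planted, rownames(expr))), 4)
  }
  genes_cmp <- .stage("genecontrast", gene_group_comparison(
    expr, meta, contrast_cluster, contrast_genes, groups = groups))
  files <- c(files, .write_tsv(genes_cmp$results,
                               file.path(out_dir, "gene_contrasts.tsv")))

  ## --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "scmeta",
    version = as.character(utils::packageVersion("scmeta")),
    config = config[setdiff(names(config), "sim")],
    sim = if (is.null(config$input_dir)) {
      cfg <- config$sim
      cfg$heterogeneity_sd <- as.data.frame(cfg$heterogeneity_sd)
      cfg[setdiff(names(cfg), "gene_ids")]
    },
    stage_counts = list(
      cells_simulated = n_simulated,
      cells_after_qc = ncol(expr),
      genes = nrow(expr),
      clusters_varied = nrow(va$table),
      genes_aged = length(unique(aged$deltas$gene)),
      aged_genes_selected = length(aged$selection$genes),
      module_sets = length(sets),
      contrast_genes_tested = nrow(genes_cmp$results),
      contrast_genes_skipped = length(genes_cmp$skipped)
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- c(files, manifest_path)

  invisible(list(qc = qc, varied = va, aged = aged, modules = mod,
                 composition = comp, gene_contrasts = genes_cmp,
                 manifest = manifest, files = files))
}
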