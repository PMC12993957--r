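# End-to-end orchestration: QC -> stratify -> geometry -> fit -> enrich ->
# aggregate -> align, with seeds, logging and QC diagnostics.

#' Pipeline configuration
#'
#' All thresholds of the analysis in one validated object. Defaults mirror
#' the standard analysis: per-stratum significance `alpha = 0.05`,
#' enrichment FDR cap 0.10, cell-type total FDR cap 0.10, PC-artifact
#' correlation threshold 0.3, dimension sweep 5..2, 1000 shuffles, 100
#' bootstrap replicates, 10% enrichment bin, 5% profile bin, donor coverage
#' 0.5, stratum size 50..1000.
#'
#' @param alpha,enrichment_fdr_cap,celltype_fdr_cap,r_threshold,dims,n_shuffles,n_boot,bin_fraction,closest_fraction,coverage_threshold,min_cells,max_cells,n_components,density_drop,seed
#'   see Description; each is validated.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, enrichment_fdr_cap = 0.10,
                            celltype_fdr_cap = 0.10, r_threshold = 0.3,
                            dims = c(5, 4, 3, 2), n_shuffles = 1000,
                            n_boot = 100, bin_fraction = 0.10,
                            closest_fraction = 0.05,
                            coverage_threshold = 0.5, min_cells = 50,
                            max_cells = 1000, n_components = 10,
                            density_drop = 0.10, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1,
            enrichment_fdr_cap > 0, enrichment_fdr_cap <= 1,
            celltype_fdr_cap > 0, celltype_fdr_cap <= 1,
            r_threshold >= 0, r_threshold <= 1,
            n_shuffles >= 1, n_boot >= 0,
            bin_fraction > 0, bin_fraction < 1,
            closest_fraction > 0, closest_fraction <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            min_cells >= 1, max_cells >= min_cells,
            density_drop >= 0, density_drop < 1)
  dims <- as.integer(dims)
  if (any(diff(dims) >= 0) || any(dims < 2) || any(dims > 5))
    stop("dims must be strictly decreasing within [2, 5]")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full polytope-discovery pipeline
#'
#' Executes, in order: rare-gene filter, QC decile filter + protein-coding
#' floor, gene stripping + 10,000-count normalization, stratification,
#' per-stratum geometry (PCA, density filter, PCA refit, correlated-
#' component drop), dimension-swept simplex fitting with shuffle tests,
#' per-vertex enrichment for significant fits, cell-type aggregation with
#' total-FDR control, and archetype alignment per cell type with at least
#' one significant fit. Fully reproducible given `config$seed`.
#'
#' @param atlas an `expression_atlas`.
#' @param config a [pipeline_config()].
#' @param verbose emit one log line per stage.
#' @param out_dir optional directory; when given, tabular artifacts are
#'   written as TSV and the summary as JSON.
#' @return List of class `pipeline_result`: `strata` (manifest data frame),
#'   `fits`, `spaces`, `strata_objects`, `pvals`, `enrichment`, `markers`,
#'   `celltype` (aggregation output), `alignments`, `qc_report`, `config`.
#' @export
run_pipeline <- function(atlas, config = pipeline_config(), verbose = FALSE,
                         out_dir = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(config, "pipeline_config"))
  seed <- config$seed

  atlas <- filter_rare_genes(atlas, 5, verbose = verbose)
  qc <- apply_cell_qc(atlas, verbose = verbose)
  natlas <- normalize_and_strip(qc$atlas, verbose = verbose)
  strata <- stratify(natlas, config$min_cells, config$max_cells,
                     seed = derive_seed(seed, 1L), qc_metrics = qc$metrics,
                     verbose = verbose)
  if (length(strata) == 0) stop("pipeline: no stratum passed the size filter")

  fits <- list(); spaces <- list(); pval_rows <- list(); skipped <- character(0)
  for (i in seq_along(strata)) {
    s <- strata[[i]]
    sp <- tryCatch(prepare_stratum_space(s, config$n_components,
                                         config$r_threshold,
                                         config$density_drop),
                   error = function(e) {
                     stage_log("geometry", s$key, "failed:",
                               conditionMessage(e), verbose = verbose)
                     NULL
                   })
    if (is.null(sp) || length(sp$pc$retained) < 2) {
      skipped <- c(skipped, s$key); next
    }
    fit <- tryCatch(
      sweep_dimensions(sp, dims = config$dims, alpha = config$alpha,
                       n_shuffles = config$n_shuffles,
                       seed = derive_seed(seed, 1000L + i),
                       stratum_id = s$key),
      error = function(e) {
        stage_log("fit", s$key, "failed:", conditionMessage(e),
                  verbose = verbose)
        NULL
      })
    if (is.null(fit)) { skipped <- c(skipped, s$key); next }
    if (config$n_boot > 0 && fit$significant) {
      fit$bootstrap <- bootstrap_vertices(fit$points, fit = fit,
                                          n_boot = config$n_boot,
                                          seed = derive_seed(seed, 2000L + i))
    }
    fits[[s$key]] <- fit
    spaces[[s$key]] <- sp
    pval_rows[[s$key]] <- cbind(fit$p_values,
                                data.frame(donor = s$donor, tissue = s$tissue,
                                           cell_type = s$cell_type,
                                           stratum_id = s$key))
    stage_log("fit", s$key, sprintf("d=%d k=%d p=%.4g%s", fit$dimension,
                                    fit$k, fit$p_value,
                                    if (fit$significant) " *" else ""),
              verbose = verbose)
  }
  if (length(fits) == 0) stop("pipeline: no stratum could be fitted")
  pvals <- do.call(rbind, pval_rows)
  rownames(pvals) <- NULL

  # enrichment for every fitted stratum; markers feed alignment
  enr <- list(); markers <- list()
  for (key in names(fits)) {
    fit <- fits[[key]]
    s <- strata[[key]]
    x_all <- s$x_all[spaces[[key]]$keep_cells, , drop = FALSE]
    tab <- vertex_enrichment(fit, x_all, config$bin_fraction)
    enr[[key]] <- tab
    markers[[key]] <- lapply(seq_len(fit$k), function(v)
      top_markers(tab, v, 10, config$enrichment_fdr_cap))
  }

  agg <- aggregate_significance(pvals, config$alpha, config$celltype_fdr_cap)

  # alignment within each cell type that has >= 1 significant fit
  meta <- do.call(rbind, lapply(names(fits), function(key) {
    s <- strata[[key]]
    data.frame(stratum_id = key, donor = s$donor, tissue = s$tissue,
               cell_type = s$cell_type,
               significant = fits[[key]]$significant,
               stringsAsFactors = FALSE)
  }))
  alignments <- list()
  for (ct in unique(meta$cell_type[meta$significant])) {
    keys <- meta$stratum_id[meta$cell_type == ct & meta$significant]
    nodes <- do.call(rbind, lapply(keys, function(key) {
      fit <- fits[[key]]
      data.frame(stratum_id = key, vertex = seq_len(fit$k),
                 donor = meta$donor[meta$stratum_id == key],
                 tissue = meta$tissue[meta$stratum_id == key],
                 stringsAsFactors = FALSE)
    }))
    nodes$markers <- unlist(lapply(keys, function(key) markers[[key]]),
                            recursive = FALSE)
    donors_avail <- unique(atlas$cell_meta$donor[atlas$cell_meta$cell_type == ct])
    alignments[[ct]] <- align_archetypes(nodes, donors_avail,
                                         config$coverage_threshold,
                                         seed = derive_seed(seed, 3000L))
  }

  manifest <- do.call(rbind, lapply(names(strata), function(key) {
    s <- strata[[key]]
    fitted <- key %in% names(fits)
    data.frame(stratum_id = key, donor = s$donor, tissue = s$tissue,
               cell_type = s$cell_type, n_cells = nrow(s$x),
               n_cells_original = s$n_cells_original, fitted = fitted,
               dimension = if (fitted) fits[[key]]$dimension else NA,
               k = if (fitted) fits[[key]]$k else NA,
               p_value = if (fitted) fits[[key]]$p_value else NA,
               significant = if (fitted) fits[[key]]$significant else NA,
               pct_inside = if (fitted) fits[[key]]$pct_inside else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL

  qc_rep <- tryCatch(qc_significance_report(manifest, strata, spaces),
                     error = function(e) NULL)

  res <- structure(list(strata = manifest, fits = fits, spaces = spaces,
                        strata_objects = strata, pvals = pvals,
                        enrichment = enr, markers = markers, celltype = agg,
                        alignments = alignments, qc_report = qc_rep,
                        skipped = skipped, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$strata), "strata,",
      sum(x$strata$significant, na.rm = TRUE), "significant fits\n")
  cat("  accepted cell types:",
      if (length(x$celltype$accepted)) paste(x$celltype$accepted, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  total FDR of accepted set: %.4f (pi0 = %.3f)\n",
              x$celltype$total_fdr, x$celltype$pi0))
  invisible(x)
}

#' QC-vs-fit diagnostic correlations
#'
#' Pearson and Spearman correlations of per-stratum QC summaries (mean
#' mitochondrial fraction, mean artifact fraction, cell count) against the
#' fit p-value and the percent of cells inside the fitted polytope. A
#' constant column yields `NA` (reported as not applicable). In a clean
#' dataset all |r| should stay weak (< 0.2).
#'
#' @param manifest stratum manifest from [run_pipeline()].
#' @param strata,spaces the pipeline's stratum and space lists.
#' @return Data frame: `metric`, `against`, `pearson`, `spearman`.
#' @export
qc_significance_report <- function(manifest, strata, spaces) {
  fitted <- manifest[manifest$fitted, , drop = FALSE]
  if (nrow(fitted) < 3) stop("need >= 3 fitted strata for the QC report")
  qc_mean <- function(key, col) {
    s <- strata[[key]]
    keep <- spaces[[key]]$keep_cells
    if (is.null(s$qc)) return(NA_real_)
    mean(s$qc[[col]][keep])
  }
  df <- data.frame(
    mean_pct_mito = vapply(fitted$stratum_id, qc_mean, numeric(1), "pct_mito"),
    mean_pct_artifact = vapply(fitted$stratum_id, qc_mean, numeric(1),
                               "pct_artifact"),
    n_cells = fitted$n_cells,
    p_value = fitted$p_value,
    pct_inside = fitted$pct_inside)
  metrics <- c("mean_pct_mito", "mean_pct_artifact", "n_cells")
  targets <- c("p_value", "pct_inside")
  rows <- list()
  for (m in metrics) for (t in targets) {
    x <- df[[m]]; y <- df[[t]]
    ok <- stats::complete.cases(x, y)
    pe <- if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok]) else NA_real_
    sp <- if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok], method = "spearman") else NA_real_
    rows[[paste(m, t)]] <- data.frame(metric = m, against = t,
                                      pearson = pe, spearman = sp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# write tabular artifacts; every number in them comes from the stage outputs
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(res$strata, "strata_manifest.tsv")
  tsv(res$pvals, "p_values.tsv")
  tsv(res$celltype$table, "celltype_significance.tsv")
  tsv(res$celltype$curve, "fdr_curve.tsv")
  if (length(res$enrichment) > 0)
    tsv(do.call(rbind, res$enrichment), "vertex_enrichment.tsv")
  if (!is.null(res$qc_report)) tsv(res$qc_report, "qc_report.tsv")
  arch_rows <- list()
  for (ct in names(res$alignments)) {
    al <- res$alignments[[ct]]
    for (cl in al$clusters) {
      arch_rows[[paste(ct, cl$cluster)]] <- data.frame(
        cell_type = ct, cluster = cl$cluster,
        n_members = nrow(cl$members), donor_coverage = cl$donor_coverage,
        accepted = cl$accepted,
        consensus_genes = paste(sprintf("%s(%d)", cl$consensus$gene,
                                        cl$consensus$frequency),
                                collapse = ","),
        annotation = cl$annotation, stringsAsFactors = FALSE)
    }
  }
  if (length(arch_rows) > 0) tsv(do.call(rbind, arch_rows), "archetypes.tsv")
  summary <- list(
    n_strata = nrow(res$strata),
    n_significant = sum(res$strata$significant, na.rm = TRUE),
    accepted_cell_types = res$celltype$accepted,
    total_fdr = res$celltype$total_fdr,
    pi0 = res$celltype$pi0,
    seed = res$config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
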