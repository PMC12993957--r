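#' Construct an expression atlas
#'
#' The container consumed by the pipeline: a sparse cells x genes count
#' matrix plus per-cell metadata (`cell_id`, `donor`, `tissue`, `cell_type`)
#' and per-gene metadata (`gene_id`, `is_protein_coding`,
#' `is_mitochondrial`, `is_artifact`).
#'
#' @param counts sparse (or dense) non-negative cells x genes matrix.
#' @param cell_meta data frame with one row per cell.
#' @param gene_meta data frame with one row per gene.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(counts, cell_meta, gene_meta) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  need_c <- c("cell_id", "donor", "tissue", "cell_type")
  need_g <- c("gene_id", "is_protein_coding", "is_mitochondrial", "is_artifact")
  if (!all(need_c %in% names(cell_meta))) stop("cell_meta must have columns: ",
                                               paste(need_c, collapse = ", "))
  if (!all(need_g %in% names(gene_meta))) stop("gene_meta must have columns: ",
                                               paste(need_g, collapse = ", "))
  if (nrow(counts) != nrow(cell_meta)) stop("counts rows != cell_meta rows")
  if (ncol(counts) != nrow(gene_meta)) stop("counts cols != gene_meta rows")
  for (fl in need_g[-1]) {
    if (!is.logical(gene_meta[[fl]])) stop(fl, " must be logical")
  }
  if (any(counts@x < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 cell_meta = as.data.frame(cell_meta),
                 gene_meta = as.data.frame(gene_meta)),
            class = "expression_atlas")
}

#' @exportS3Method base::print
print.expression_atlas <- function(x, ...) {
  cat("expression_atlas:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  donors:", length(unique(x$cell_meta$donor)),
      " tissues:", length(unique(x$cell_meta$tissue)),
      " cell types:", length(unique(x$cell_meta$cell_type)), "\n")
  invisible(x)
}

#' Remove genes expressed in too few cells
#'
#' @param atlas an `expression_atlas`.
#' @param min_cells minimum number of cells with a nonzero count for a gene
#'   to be retained (default 5).
#' @param verbose emit a log line.
#' @return The filtered atlas.
#' @export
filter_rare_genes <- function(atlas, min_cells = 5, verbose = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"), min_cells >= 0)
  support <- Matrix::colSums(atlas$counts > 0)
  keep <- support >= min_cells
  if (!any(keep)) stop("rare-gene filter removed all genes")
  stage_log("filter_rare_genes", "removed", sum(!keep), "of", length(keep),
            "genes", verbose = verbose)
  expression_atlas(atlas$counts[, keep, drop = FALSE], atlas$cell_meta,
                   atlas$gene_meta[keep, , drop = FALSE])
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell: percent mitochondrial counts, percent artifact counts,
#' number of genes expressed, total counts, number of UMI counts (identical
#' to total counts for pure-UMI input, kept to mirror the standard metric
#' list), and protein-coding counts excluding mitochondrial/artifact genes.
#' Cells with zero total counts get both percentages set to 0 and are
#' flagged.
#'
#' @param atlas an `expression_atlas`.
#' @return A data frame of QC metrics, one row per cell.
#' @export
compute_qc_metrics <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  g <- atlas$gene_meta
  tot <- Matrix::rowSums(atlas$counts)
  mito <- Matrix::rowSums(atlas$counts[, g$is_mitochondrial, drop = FALSE])
  art <- Matrix::rowSums(atlas$counts[, g$is_artifact, drop = FALSE])
  pc_sel <- g$is_protein_coding & !g$is_mitochondrial & !g$is_artifact
  pc <- Matrix::rowSums(atlas$counts[, pc_sel, drop = FALSE])
  zero <- tot == 0
  data.frame(cell_id = atlas$cell_meta$cell_id,
             pct_mito = ifelse(zero, 0, mito / pmax(tot, 1e-300)),
             pct_artifact = ifelse(zero, 0, art / pmax(tot, 1e-300)),
             n_genes_expressed = Matrix::rowSums(atlas$counts > 0),
             total_counts = tot,
             n_umi = tot,
             protein_coding_counts = pc,
             zero_total = zero,
             stringsAsFactors = FALSE)
}

#' Upper-decile cell filter
#'
#' A cell is removed iff its value strictly exceeds the 90th percentile
#' (linear-interpolation quantile) of ANY of the listed metrics. With a
#' constant metric nothing is removed on that metric.
#'
#' @param metrics data frame from [compute_qc_metrics()].
#' @param metric_names metrics to screen (default: the five standard ones).
#' @return Logical keep mask aligned with `metrics`.
#' @export
filter_upper_decile <- function(metrics,
                                metric_names = c("pct_mito", "pct_artifact",
                                                 "n_genes_expressed",
                                                 "total_counts", "n_umi")) {
  keep <- rep(TRUE, nrow(metrics))
  for (m in metric_names) {
    v <- metrics[[m]]
    if (is.null(v)) stop("unknown metric: ", m)
    q90 <- stats::quantile(v, 0.9, type = 7, names = FALSE)
    keep <- keep & (v <= q90)
  }
  keep
}

#' Protein-coding count floor
#'
#' Lists cells whose protein-coding counts (excluding mitochondrial and
#' artifact genes) are at or below the threshold. The threshold mirrors an
#' a-priori 100-count floor; violators are reported so the caller can remove
#' and log them.
#'
#' @param metrics data frame from [compute_qc_metrics()].
#' @param threshold counts at or below this value violate (default 100).
#' @return Character vector of violating cell ids.
#' @export
assert_min_protein_coding <- function(metrics, threshold = 100) {
  metrics$cell_id[metrics$protein_coding_counts <= threshold]
}

#' Apply the standard cell QC filters
#'
#' Runs the upper-decile filter on the five QC metrics and the
#' protein-coding floor, in that order, and returns the filtered atlas.
#'
#' @param atlas an `expression_atlas`.
#' @param threshold protein-coding count floor.
#' @param verbose emit log lines.
#' @return List with `atlas` (filtered), `metrics` (post-filter QC metrics),
#'   and `removed` (per-filter counts).
#' @export
apply_cell_qc <- function(atlas, threshold = 100, verbose = FALSE) {
  metrics <- compute_qc_metrics(atlas)
  keep1 <- filter_upper_decile(metrics)
  stage_log("filter_upper_decile", "removed", sum(!keep1), "of", length(keep1),
            "cells", verbose = verbose)
  atlas2 <- expression_atlas(atlas$counts[keep1, , drop = FALSE],
                             atlas$cell_meta[keep1, , drop = FALSE],
                             atlas$gene_meta)
  m2 <- metrics[keep1, , drop = FALSE]
  viol <- assert_min_protein_coding(m2, threshold)
  stage_log("protein_coding_floor", "removed", length(viol), "cells",
            verbose = verbose)
  keep2 <- !(m2$cell_id %in% viol)
  atlas3 <- expression_atlas(atlas2$counts[keep2, , drop = FALSE],
                             atlas2$cell_meta[keep2, , drop = FALSE],
                             atlas2$gene_meta)
  list(atlas = atlas3, metrics = m2[keep2, , drop = FALSE],
       removed = c(upper_decile = sum(!keep1), protein_floor = length(viol)))
}

#' Strip mitochondrial/artifact genes and normalize to 10,000 counts per cell
#'
#' The modeling matrix keeps protein-coding genes excluding mitochondrial and
#' artifact genes; each cell is scaled so its retained counts sum to 10,000.
#' A parallel all-genes matrix is scaled by the same per-cell factors so that
#' enrichment sees mitochondrial/artifact genes on a comparable scale.
#' Zero-count cells (on the modeling genes) are removed with a log entry.
#'
#' @param atlas an `expression_atlas` (after QC filters).
#' @param target per-cell target sum (default 10,000).
#' @param verbose emit log lines.
#' @return A list of class `normalized_atlas`: `norm` (cells x modeling
#'   genes), `norm_all` (cells x all genes, same scale factors), `cell_meta`,
#'   `gene_meta` (all genes), `model_genes` (ids), `scale_factors`.
#' @export
normalize_and_strip <- function(atlas, target = 1e4, verbose = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  g <- atlas$gene_meta
  model_sel <- g$is_protein_coding & !g$is_mitochondrial & !g$is_artifact
  mod <- atlas$counts[, model_sel, drop = FALSE]
  tot <- Matrix::rowSums(mod)
  keep <- tot > 0
  stage_log("normalize_and_strip", "removed", sum(!keep), "zero-count cells;",
            sum(model_sel), "modeling genes", verbose = verbose)
  mod <- mod[keep, , drop = FALSE]
  sf <- target / tot[keep]
  norm <- Matrix::Matrix(mod * sf, sparse = TRUE)
  norm_all <- Matrix::Matrix(atlas$counts[keep, , drop = FALSE] * sf, sparse = TRUE)
  structure(list(norm = norm, norm_all = norm_all,
                 cell_meta = atlas$cell_meta[keep, , drop = FALSE],
                 gene_meta = g,
                 model_genes = g$gene_id[model_sel],
                 scale_factors = sf),
            class = "normalized_atlas")
}

#' Stratify a normalized atlas into donor-tissue-cell-type units
#'
#' One stratum per (donor, tissue, cell type) with at least `min_cells`
#' cells; larger strata are uniformly subsampled without replacement to
#' `max_cells`, seeded. Undersized groups are logged and skipped.
#'
#' @param natlas a `normalized_atlas` from [normalize_and_strip()].
#' @param min_cells minimum stratum size (default 50).
#' @param max_cells downsampling cap (default 1000).
#' @param seed integer seed for the subsampling.
#' @param qc_metrics optional QC metric data frame (rows matched by
#'   `cell_id`) carried along per stratum for diagnostics.
#' @param verbose emit log lines.
#' @return List of `stratum` objects: `donor`, `tissue`, `cell_type`, `key`,
#'   `x` (dense cells x modeling genes), `x_all` (dense, all genes),
#'   `n_cells_original`, `qc`.
#' @export
stratify <- function(natlas, min_cells = 50, max_cells = 1000, seed = 1L,
                     qc_metrics = NULL, verbose = FALSE) {
  stopifnot(inherits(natlas, "normalized_atlas"))
  cm <- natlas$cell_meta
  key <- paste(cm$donor, cm$tissue, cm$cell_type, sep = "|")
  groups <- split(seq_len(nrow(cm)), key)
  strata <- list()
  counter <- 0L
  for (k in sort(names(groups))) {
    idx <- groups[[k]]
    counter <- counter + 1L
    if (length(idx) < min_cells) {
      stage_log("stratify", "skipping", k, "with", length(idx), "cells",
                verbose = verbose)
      next
    }
    n_orig <- length(idx)
    if (length(idx) > max_cells) {
      set.seed(derive_seed(seed, counter))
      idx <- sort(sample(idx, max_cells))
    }
    qc <- NULL
    if (!is.null(qc_metrics)) {
      qc <- qc_metrics[match(cm$cell_id[idx], qc_metrics$cell_id), , drop = FALSE]
    }
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    strata[[k]] <- structure(list(donor = parts[1], tissue = parts[2],
                                  cell_type = parts[3], key = k,
                                  x = as.matrix(natlas$norm[idx, , drop = FALSE]),
                                  x_all = as.matrix(natlas$norm_all[idx, , drop = FALSE]),
                                  cell_ids = cm$cell_id[idx],
                                  n_cells_original = n_orig,
                                  qc = qc),
                             class = "stratum")
  }
  stage_log("stratify", length(strata), "strata of", length(groups), "groups",
            verbose = verbose)
  strata
}

#' @exportS3Method base::print
print.stratum <- function(x, ...) {
  cat("stratum", x$key, ":", nrow(x$x), "cells x", ncol(x$x),
      "modeling genes\n")
  invisible(x)
}
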