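#' Linear-scale PCA of a stratum
#'
#' PCA on mean-centered, unscaled, unlogged normalized expression. Common
#' single-cell transforms (log, per-gene scaling) distort pairwise distances
#' and are deliberately avoided: the polytope geometry is only meaningful in
#' a space where distances are preserved. A deterministic sign convention
#' (largest-magnitude loading positive) makes scores reproducible across
#' platforms.
#'
#' @param x cells x genes matrix (a stratum's normalized matrix), or a
#'   `stratum` object.
#' @param n_components number of components to compute (default 10); reduced
#'   with a warning if the matrix rank is lower.
#' @return An object of class `pc_space`: `scores` (cells x components),
#'   `loadings` (genes x components), `explained_variance` (per-component
#'   variance), `center`, `retained` (component indices currently in use),
#'   `dropped` (data frame, initially empty).
#' @export
pca_linear <- function(x, n_components = 10) {
  if (inherits(x, "stratum")) x <- x$x
  x <- as.matrix(x)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warning("rank limits components to ", max_rank)
    n_components <- max_rank
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  # drop numerically null components
  pos <- p$sdev[seq_len(n_components)] > 1e-12 * max(p$sdev[1], 1e-300)
  if (!all(pos)) {
    warning("rank-deficient input: keeping ", sum(pos), " components")
    n_components <- sum(pos)
  }
  load <- p$rotation[, seq_len(n_components), drop = FALSE]
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = load,
                 explained_variance = p$sdev[seq_len(n_components)]^2,
                 center = p$center,
                 retained = seq_len(n_components),
                 dropped = data.frame(component = integer(0),
                                      r_mito = numeric(0),
                                      r_artifact = numeric(0))),
            class = "pc_space")
}

#' @exportS3Method base::print
print.pc_space <- function(x, ...) {
  cat("pc_space:", nrow(x$scores), "cells,", ncol(x$scores), "components (",
      length(x$retained), "retained )\n")
  invisible(x)
}

# Pearson correlation treating constant vectors as uncorrelated.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Drop principal components correlated with technical signals
#'
#' A component is retained iff its absolute Pearson correlation with BOTH
#' the per-cell mitochondrial fraction and the artifact fraction is at most
#' `r_threshold` (strictly greater drops, so r exactly at the threshold is
#' retained). Order of retained components is preserved.
#'
#' @param pc a `pc_space`.
#' @param pct_mito,pct_artifact per-cell fractions aligned with the score
#'   rows.
#' @param r_threshold correlation threshold (default 0.3).
#' @return The `pc_space` with `retained`/`dropped` updated.
#' @export
drop_correlated_components <- function(pc, pct_mito, pct_artifact,
                                       r_threshold = 0.3) {
  stopifnot(inherits(pc, "pc_space"))
  n <- nrow(pc$scores)
  if (length(pct_mito) != n || length(pct_artifact) != n)
    stop("signal vectors must align with cells")
  rm_ <- vapply(pc$retained, function(j) safe_cor(pc$scores[, j], pct_mito),
                numeric(1))
  ra <- vapply(pc$retained, function(j) safe_cor(pc$scores[, j], pct_artifact),
               numeric(1))
  bad <- abs(rm_) > r_threshold | abs(ra) > r_threshold
  pc$dropped <- rbind(pc$dropped,
                      data.frame(component = pc$retained[bad],
                                 r_mito = rm_[bad], r_artifact = ra[bad]))
  pc$retained <- pc$retained[!bad]
  pc
}

#' Density-based outlier removal in leading PC space
#'
#' Estimates per-cell density as the inverse distance to the k-th nearest
#' neighbour (k = ceiling(sqrt(n))) in the first `n_components` components
#' and removes exactly `floor(drop_fraction * n)` lowest-density cells.
#' Duplicate points share identical density; ties are broken by cell index.
#'
#' @param scores cells x components score matrix (or a `pc_space`).
#' @param n_components how many leading components define the density space
#'   (default 3; all available if fewer).
#' @param drop_fraction fraction of cells to remove (default 0.10).
#' @return Logical keep mask.
#' @export
density_filter <- function(scores, n_components = 3, drop_fraction = 0.10) {
  if (inherits(scores, "pc_space")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (drop_fraction < 0 || drop_fraction >= 1) stop("drop_fraction in [0, 1)")
  n_drop <- floor(drop_fraction * n)
  if (n_drop == 0) return(rep(TRUE, n))
  d <- min(n_components, ncol(scores))
  k <- min(ceiling(sqrt(n)), n - 1L)
  dm <- as.matrix(stats::dist(scores[, seq_len(d), drop = FALSE]))
  kdist <- apply(dm, 1, function(r) sort(r)[k + 1L])  # k-th neighbour, self excluded
  dens <- 1 / pmax(kdist, 1e-300)
  drop_idx <- order(dens, seq_len(n))[seq_len(n_drop)]
  keep <- rep(TRUE, n)
  keep[drop_idx] <- FALSE
  keep
}

#' Prepare a stratum's fitting space
#'
#' The geometry stage applied to one stratum: (1) PCA on the normalized
#' modeling matrix, (2) removal of the bottom 10% density cells in the first
#' 3 components, (3) PCA refit on the surviving cells (stabilizing the
#' transformation), (4) removal of components correlated (|r| > 0.3) with
#' mitochondrial or artifact expression. The stratum's raw matrices are
#' never modified; the returned object records which cells survived.
#'
#' @param stratum a `stratum` from [stratify()] (must carry `qc` metrics for
#'   the correlation filter; without them step 4 is skipped with a warning).
#' @param n_components components to compute (default 10).
#' @param r_threshold correlation threshold (default 0.3).
#' @param drop_fraction density-filter fraction (default 0.10).
#' @return List of class `stratum_space`: `pc` (the post-filter `pc_space`),
#'   `keep_cells` (logical over the stratum's cells), `stratum`.
#' @export
prepare_stratum_space <- function(stratum, n_components = 10,
                                  r_threshold = 0.3, drop_fraction = 0.10) {
  stopifnot(inherits(stratum, "stratum"))
  pc0 <- pca_linear(stratum$x, n_components)
  keep <- density_filter(pc0$scores, 3, drop_fraction)
  pc <- pca_linear(stratum$x[keep, , drop = FALSE], n_components)
  if (!is.null(stratum$qc)) {
    pc <- drop_correlated_components(pc, stratum$qc$pct_mito[keep],
                                     stratum$qc$pct_artifact[keep],
                                     r_threshold)
  } else {
    warning("stratum has no QC metrics; skipping correlated-component filter")
  }
  structure(list(pc = pc, keep_cells = keep, stratum = stratum),
            class = "stratum_space")
}

# score matrix restricted to retained components, in retained order
retained_scores <- function(pc) {
  pc$scores[, pc$retained, drop = FALSE]
}
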