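# Per-vertex marker-gene enrichment: cells nearest a vertex vs the rest.

#' Order cells by distance to a vertex
#'
#' Ascending Euclidean distance in the fit's PC space; ties broken by cell
#' index.
#'
#' @param scores cells x d score matrix (same space as the fit).
#' @param vertex length-d vertex coordinates.
#' @return Integer ordering of the cells.
#' @export
rank_cells_by_vertex_distance <- function(scores, vertex) {
  scores <- as.matrix(scores)
  d <- sqrt(rowSums(sweep(scores, 2, vertex)^2))
  order(d, seq_along(d))
}

# Vectorized one-sided Mann-Whitney U (group1 > group2) over the columns of
# X. Exact null distribution (stats::pwilcox) when both groups are small and
# the column has no ties; otherwise normal approximation with tie correction
# and continuity correction, matching stats::wilcox.test conventions.
mann_whitney_columns <- function(X, idx1) {
  X <- as.matrix(X)
  n <- nrow(X)
  n1 <- length(idx1)
  n2 <- n - n1
  in1 <- seq_len(n) %in% idx1
  p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (max(v) == min(v)) { p[j] <- 1; next }
    r <- rank(v)
    U1 <- sum(r[in1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (!has_ties && n1 <= 25 && n2 <= 25) {
      p[j] <- 1 - stats::pwilcox(U1 - 1, n1, n2)
    } else {
      mu <- n1 * n2 / 2
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
      if (sig == 0) { p[j] <- 1; next }
      z <- (U1 - mu - 0.5) / sig
      p[j] <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  p
}

#' Gene enrichment at one vertex
#'
#' One-sided Mann-Whitney test per gene of the cells in the nearest bin
#' (first `bin_fraction` of the distance ordering, at least 10 cells)
#' against the remaining cells, on normalized expression over ALL genes
#' (mitochondrial and artifact genes included, so artifactual vertices can
#' be detected). The effect size is the difference of mean normalized
#' expression (nearest bin minus rest). Constant genes get `p = 1` and
#' effect 0.
#'
#' @param all_genes_matrix cells x genes normalized matrix (all genes).
#' @param ordering cell ordering from [rank_cells_by_vertex_distance()].
#' @param bin_fraction fraction of cells forming the nearest bin
#'   (default 0.10).
#' @return Data frame: `gene_id`, `effect_size`, `p`.
#' @export
enrich_vertex <- function(all_genes_matrix, ordering, bin_fraction = 0.10) {
  X <- as.matrix(all_genes_matrix)
  n <- nrow(X)
  n_bin <- max(10L, ceiling(bin_fraction * n))
  if (n_bin >= n) stop("nearest bin would cover all cells")
  bin_idx <- ordering[seq_len(n_bin)]
  p <- mann_whitney_columns(X, bin_idx)
  eff <- colMeans(X[bin_idx, , drop = FALSE]) -
    colMeans(X[-bin_idx, , drop = FALSE])
  const <- apply(X, 2, function(v) max(v) == min(v))
  eff[const] <- 0
  gid <- colnames(X) %||% sprintf("g%d", seq_len(ncol(X)))
  data.frame(gene_id = gid, effect_size = unname(eff), p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard step-up q-values `q_(i) = min_(j>=i) p_(j) m / j`, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values aligned with the input.
#' @export
bh_correct <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment table for every vertex of a fit
#'
#' Runs [enrich_vertex()] for each vertex and applies the BH correction per
#' vertex across genes. Rows are sorted by (vertex, q, -effect_size).
#'
#' @param fit a `polytope_fit`.
#' @param all_genes_matrix cells x genes normalized matrix aligned with the
#'   fit's cells.
#' @param bin_fraction nearest-bin fraction (default 0.10).
#' @param stratum_id optional identifier.
#' @return Data frame (`VertexEnrichmentTable`): `stratum_id`, `vertex`,
#'   `gene_id`, `effect_size`, `p`, `q`, `rank`.
#' @export
vertex_enrichment <- function(fit, all_genes_matrix, bin_fraction = 0.10,
                              stratum_id = fit$stratum_id) {
  stopifnot(inherits(fit, "polytope_fit"))
  X <- as.matrix(all_genes_matrix)
  if (nrow(X) != nrow(fit$points))
    stop("expression matrix must align with the fitted cells")
  out <- lapply(seq_len(fit$k), function(v) {
    ord <- rank_cells_by_vertex_distance(fit$points, fit$vertices[v, ])
    e <- enrich_vertex(X, ord, bin_fraction)
    e$q <- bh_correct(e$p)
    e <- e[order(e$q, -e$effect_size, e$gene_id), , drop = FALSE]
    e$rank <- seq_len(nrow(e))
    cbind(stratum_id = stratum_id %||% NA_character_, vertex = v, e)
  })
  do.call(rbind, out)
}

#' Top marker genes of a vertex
#'
#' Among genes with `q <= fdr` and positive effect size, up to `n` genes by
#' descending effect size (ties by gene id). A vertex with no significant
#' genes returns an empty list and is flagged as a candidate false-positive
#' polytope.
#'
#' @param table a `VertexEnrichmentTable` from [vertex_enrichment()].
#' @param vertex vertex index.
#' @param n maximum markers (default 10).
#' @param fdr q-value cap (default 0.10).
#' @return Character vector of gene ids (possibly empty, with attribute
#'   `flagged = TRUE` when empty).
#' @export
top_markers <- function(table, vertex, n = 10, fdr = 0.10) {
  t_v <- table[table$vertex == vertex & table$q <= fdr &
                 table$effect_size > 0, , drop = FALSE]
  t_v <- t_v[order(-t_v$effect_size, t_v$gene_id), , drop = FALSE]
  out <- utils::head(t_v$gene_id, n)
  if (length(out) == 0) attr(out, "flagged") <- TRUE
  out
}
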