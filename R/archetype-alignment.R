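# Cross-donor-tissue alignment of vertices (specialist phenotypes) within a
# cell type, by shared enriched genes.

#' Vertex-sharing adjacency matrix
#'
#' Weight between two specialist phenotypes is the number of genes shared
#' between their marker lists (plain set intersection); zero-weight pairs
#' carry no edge. Diagonal is zero.
#'
#' @param marker_lists list of character vectors (one per vertex node).
#' @return Symmetric integer matrix.
#' @export
build_vertex_graph <- function(marker_lists) {
  n <- length(marker_lists)
  if (n < 2) stop("need at least 2 vertex nodes")
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- length(intersect(marker_lists[[i]], marker_lists[[j]]))
      A[i, j] <- A[j, i] <- w
    }
  }
  dimnames(A) <- list(names(marker_lists), names(marker_lists))
  A
}

#' Cluster vertices on the shared-gene graph
#'
#' Louvain community detection on the weighted graph (resolution 1, seeded).
#' Isolated vertices become singleton clusters. Redundant vertices from a
#' single donor-tissue may legitimately co-cluster; the donor-coverage
#' filter downstream ensures they cannot by themselves create an archetype.
#'
#' @param adjacency symmetric weight matrix from [build_vertex_graph()].
#' @param seed integer seed.
#' @return Integer cluster labels (one per node).
#' @export
cluster_vertices <- function(adjacency, seed = 1L) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  if (igraph::ecount(g) == 0) return(seq_len(nrow(adjacency)))
  comm <- igraph::cluster_louvain(g, resolution = 1)
  igraph::membership(comm)
}

#' Donor-coverage filter for vertex clusters
#'
#' A cluster is accepted iff the distinct donors it contains cover at least
#' `threshold` of the cell type's available donors (default 0.5; the
#' stricter two-thirds variant is `threshold = 2/3`). Counting distinct
#' donors means redundant vertices from one donor-tissue never inflate
#' coverage.
#'
#' @param labels cluster labels per node.
#' @param donors donor of each node.
#' @param donors_available all donors available for the cell type.
#' @param threshold coverage fraction (default 0.5).
#' @return Data frame: `cluster`, `n_members`, `n_donors`, `coverage`,
#'   `accepted`.
#' @export
coverage_filter <- function(labels, donors, donors_available, threshold = 0.5) {
  D <- length(unique(donors_available))
  out <- lapply(sort(unique(labels)), function(cl) {
    sel <- labels == cl
    nd <- length(unique(donors[sel]))
    data.frame(cluster = cl, n_members = sum(sel), n_donors = nd,
               coverage = nd / D, accepted = nd / D >= threshold)
  })
  do.call(rbind, out)
}

#' Consensus gene list of a cluster
#'
#' Genes ranked by descending frequency across the member marker lists;
#' frequency-one genes are dropped (a gene seen in a single specialist
#' phenotype is not reproducible). Ties by gene id.
#'
#' @param marker_lists marker lists of the cluster members (>= 2).
#' @return Data frame `gene`, `frequency` (possibly 0 rows, then flagged
#'   via attribute `flagged`).
#' @export
consensus_genes <- function(marker_lists) {
  if (length(marker_lists) < 2) stop("consensus needs >= 2 members")
  tab <- table(unlist(marker_lists))
  tab <- tab[tab >= 2]
  out <- data.frame(gene = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) attr(out, "flagged") <- TRUE
  out
}

#' Align specialist phenotypes into archetypes for one cell type
#'
#' Builds the shared-gene graph over all vertex nodes of a cell type,
#' clusters it, applies the donor-coverage filter, and computes consensus
#' gene lists. Nodes with empty marker lists are excluded (they cannot
#' share genes) and reported.
#'
#' @param nodes data frame with columns `stratum_id`, `vertex`, `donor`,
#'   `tissue`, and a list-column `markers` (character vectors, <= 10 genes).
#' @param donors_available donors available for the cell type.
#' @param threshold coverage threshold (default 0.5).
#' @param seed clustering seed.
#' @param annotate optional hook: a function taking a character vector of
#'   genes and returning a label; the default returns `"unannotated"`.
#' @return List of class `archetype_alignment`: `clusters` (list of
#'   `archetype_cluster` records), `labels`, `coverage`, `excluded_nodes`.
#' @export
align_archetypes <- function(nodes, donors_available, threshold = 0.5,
                             seed = 1L, annotate = NULL) {
  stopifnot(is.data.frame(nodes), "markers" %in% names(nodes))
  empty <- vapply(nodes$markers, length, integer(1)) == 0
  excluded <- nodes[empty, , drop = FALSE]
  nodes <- nodes[!empty, , drop = FALSE]
  if (nrow(nodes) < 2) {
    return(structure(list(clusters = list(),
                          labels = integer(0),
                          coverage = NULL, excluded_nodes = excluded),
                     class = "archetype_alignment"))
  }
  A <- build_vertex_graph(nodes$markers)
  labels <- cluster_vertices(A, seed = seed)
  cov <- coverage_filter(labels, nodes$donor, donors_available, threshold)
  clusters <- lapply(seq_len(nrow(cov)), function(i) {
    cl <- cov$cluster[i]
    sel <- which(labels == cl)
    cons <- if (length(sel) >= 2) consensus_genes(nodes$markers[sel])
            else data.frame(gene = character(0), frequency = integer(0))
    genes <- cons$gene
    ann <- if (!is.null(annotate) && length(genes) > 0) annotate(genes)
           else "unannotated"
    structure(list(cluster = cl,
                   members = nodes[sel, c("stratum_id", "vertex", "donor",
                                          "tissue")],
                   member_markers = nodes$markers[sel],
                   donor_coverage = cov$coverage[i],
                   consensus = cons,
                   accepted = cov$accepted[i],
                   annotation = ann),
              class = "archetype_cluster")
  })
  structure(list(clusters = clusters, labels = labels, coverage = cov,
                 excluded_nodes = excluded),
            class = "archetype_alignment")
}

#' @exportS3Method base::print
print.archetype_alignment <- function(x, ...) {
  acc <- sum(vapply(x$clusters, `[[`, logical(1), "accepted"))
  cat("archetype_alignment:", length(x$clusters), "clusters (", acc,
      "accepted ) over", length(x$labels), "vertex nodes\n")
  invisible(x)
}

#' Archetype expression profiles over consensus genes
#'
#' For each accepted archetype cluster, pools the `closest_fraction` of
#' cells nearest each member vertex (per donor-tissue stratum) and averages
#' their normalized expression of the cluster's consensus genes. The same
#' genes' means in every other cluster are reported alongside, so own- vs
#' other-archetype expression can be compared.
#'
#' @param alignment an `archetype_alignment`.
#' @param fits named list of `polytope_fit` objects (by stratum id).
#' @param strata named list of `stratum` objects (by stratum id), supplying
#'   `x_all` with gene columns; row subsets must match the fitted cells via
#'   `keep_cells` stored in `spaces`.
#' @param spaces named list of `stratum_space` objects (by stratum id).
#' @param closest_fraction fraction of closest cells per vertex
#'   (default 0.05).
#' @return List: `profile` (clusters x genes own-archetype means), `other`
#'   (same genes, mean over all other clusters' pooled cells), `genes`.
#' @export
archetype_expression_profile <- function(alignment, fits, strata, spaces,
                                         closest_fraction = 0.05) {
  clusters <- alignment$clusters
  if (length(clusters) == 0) stop("no clusters to profile")
  genes <- unique(unlist(lapply(clusters, function(cl) cl$consensus$gene)))
  if (length(genes) == 0) stop("no consensus genes")
  # pooled expression per cluster over the union of consensus genes
  pool <- lapply(clusters, function(cl) {
    mats <- lapply(seq_len(nrow(cl$members)), function(i) {
      sid <- cl$members$stratum_id[i]
      v <- cl$members$vertex[i]
      fit <- fits[[sid]]
      sp <- spaces[[sid]]
      x_all <- strata[[sid]]$x_all[sp$keep_cells, , drop = FALSE]
      ord <- rank_cells_by_vertex_distance(fit$points, fit$vertices[v, ])
      n_take <- max(1L, ceiling(closest_fraction * length(ord)))
      x_all[ord[seq_len(n_take)], genes, drop = FALSE]
    })
    do.call(rbind, mats)
  })
  profile <- t(vapply(pool, colMeans, numeric(length(genes))))
  rownames(profile) <- vapply(clusters, function(cl) paste0("A", cl$cluster),
                              character(1))
  other <- profile
  for (i in seq_along(pool)) {
    rest <- do.call(rbind, pool[-i])
    other[i, ] <- if (is.null(rest)) NA_real_ else colMeans(rest)
  }
  list(profile = profile, other = other, genes = genes)
}
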